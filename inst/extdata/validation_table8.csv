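response,medium,mean,sd,n,letters
SN,R,3.6,1.12,45,
SN,MS,3.60,1.01,45,
SN,B5,3.51,1.10,45,
SN,St,4.10,1.16,45,
SN,Ha,4.04,0.82,45,
SL,R,2.69,0.55,45,b
SL,MS,1.72,0.40,45,d
SL,B5,1.88,0.35,45,d
SL,St,3.41,1.20,45,a
SL,Ha,2.10,0.60,45,cd
LA,R,34.06,10.29,45,bc
LA,MS,29.58,7.62,45,cd
LA,B5,21.43,6.86,45,e
LA,St,43.05,8.57,45,a
LA,Ha,38.39,11.04,45,ab
SQ,R,4.51,0.51,45,a
SQ,MS,4.13,0.7,45,b
SQ,B5,3.22,0.60,45,c
SQ,St,4.02,0.27,45,ab
SQ,Ha,3.87,0.46,45,b
BC,R,4.00,0.00,45,a
BC,MS,4.00,0.00,45,a
BC,B5,3.00,0.00,45,c
BC,St,3.60,0.50,45,b
BC,Ha,4.00,0.00,45,a
H,R,2.80,0.46,45,
H,MS,2.64,0.68,45,
H,B5,2.80,0.55,45,
H,St,2.67,0.53,45,
H,Ha,2.60,0.69,45,
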