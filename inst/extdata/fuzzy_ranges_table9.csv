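ion,output,level,lo,hi
NH4,SN,Low,4.12,12.37
NH4,SN,High,12.37,20.61
NH4,BC,Low,4.12,8.25
NH4,BC,Mid,8.25,16.49
NH4,BC,High,16.49,20.61
NO3,SN,Low,6.00,22.71
NO3,SN,High,22.71,39.41
NO3,LA,Low,6.00,22.71
NO3,LA,High,22.71,39.41
NO3,SQ,Low,6.00,14.35
NO3,SQ,Mid,14.35,31.06
NO3,SQ,High,31.06,39.41
K,SL,Low,2.19,12.37
K,SL,High,12.37,22.55
K,SQ,Low,2.19,12.37
K,SQ,High,12.37,22.55
Mg,SL,Low,0.38,1.41
Mg,SL,Mid,1.41,3.47
Mg,SL,High,3.47,4.50
PO4,SL,Low,0.31,1.17
PO4,SL,Mid,1.17,2.89
PO4,SL,High,2.89,3.75
PO4,BC,Low,0.31,1.17
PO4,BC,Mid,1.17,2.89
PO4,BC,High,2.89,3.75
SO4,SN,Low,0.49,2.85
SO4,SN,High,2.85,5.20
SO4,SQ,Low,0.49,1.67
SO4,SQ,Mid,2.85,4.02
SO4,SQ,High,4.02,5.20
SO4,BC,Low,0.49,1.67
SO4,BC,Mid,2.85,4.02
SO4,BC,High,4.02,5.20
SO4,H,Low,0.49,2.85
SO4,H,High,2.85,5.20
Cl,LA,Low,1.50,9.73
Cl,LA,High,9.73,17.96
Cl,H,Low,1.50,9.73
Cl,H,High,9.73,17.96
Fe,SL,Low,0.10,0.30
Fe,SL,High,0.30,0.50
Fe,SQ,Low,0.10,0.30
Fe,SQ,High,0.30,0.50
BO3,SN,Low,0.01,0.08
BO3,SN,High,0.08,0.15
BO3,SL,Low,0.01,0.05
BO3,SL,Mid,0.05,0.12
BO3,SL,High,0.12,0.15
BO3,SQ,Low,0.01,0.05
BO3,SQ,Mid,0.05,0.12
BO3,SQ,High,0.12,0.15
BO3,H,Low,0.01,0.08
BO3,H,High,0.08,0.15
MoO2,SN,Low,0.0001,0.0008
MoO2,SN,High,0.0008,0.0016
Na,SN,Low,0.20,0.60
Na,SN,High,0.60,1.00
Na,LA,Low,0.20,0.60
Na,LA,High,0.60,1.00
I,SN,Low,0.001,0.002
I,SN,Mid,0.002,0.06
I,SN,High,0.006,0.008
I,H,Low,0.001,0.004
I,H,High,0.004,0.008
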