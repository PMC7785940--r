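component,type,R,MS,B5,St,Ha
KNO3,mineral,1604.18,1900,2500,1800,1900
NH4NO3,mineral,1297.09,1650,,400,1650
(NH4)2SO4,mineral,,,134,,
Ca(NO3)2.4H2O,mineral,,,,1200,
CaCl2.2H2O,mineral,545.61,440,150,,440
MgSO4.7H2O,mineral,926.54,370,250,360,370
KH2PO4,mineral,375.63,170,,270,170
NaH2PO4.H2O,mineral,,,150,,
MnSO4.4H2O,mineral,5.63,22.30,13.20,1.0,25.00
ZnSO4.7H2O,mineral,2.97,8.60,2.00,8.60,10.00
H3BO3,mineral,5.07,6.20,3.00,6.20,10.00
KI,mineral,1.43,0.83,0.75,0.08,
CuSO4.5H2O,mineral,0.05,0.025,0.025,0.025,0.025
Na2MoO4.2H2O,mineral,0.28,0.25,0.25,0.25,0.25
CoCl2.6H2O,mineral,0.04,0.025,0.025,0.025,
FeSO4.7H2O,mineral,49.54,27.85,27.85,27.85,27.85
Na2EDTA.2H2O,mineral,53.88,37.25,37.25,37.25,37.25
Myo-inositol,vitamin,100,100,100,100,500
Thiamine-HCl,vitamin,0.1,0.1,10.0,4.0,0.5
Nicotinic-acid,vitamin,0.5,0.5,1.0,,5.0
Pyridoxine-HCl,vitamin,0.5,0.5,1.0,,0.5
Biotine,vitamin,,,,,0.05
Folic acid,vitamin,,,,,0.5
Glycine,vitamin,2.0,2.0,,,2.0
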