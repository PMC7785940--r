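salt,formula,molar_mass,NH4,NO3,K,Ca,Mg,PO4,SO4,Cl,Fe,BO3,Mn,Zn,Cu,MoO2,Na,Co,I,EDTA
NH4NO3,NH4NO3,80.04,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
KNO3,KNO3,101.10,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
CaCl2.2H2O,CaCl2·2H2O,147.02,0,0,0,1,0,0,0,2,0,0,0,0,0,0,0,0,0,0
MgSO4.7H2O,MgSO4·7H2O,246.48,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0
KH2PO4,KH2PO4,136.09,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
MnSO4.4H2O,MnSO4·4H2O,223.06,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0
ZnSO4.7H2O,ZnSO4·7H2O,287.56,0,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0
H3BO3,H3BO3,61.83,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0
KI,KI,166.00,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0
CuSO4.5H2O,CuSO4·5H2O,249.69,0,0,0,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0
Na2MoO4.2H2O,Na2MoO4·2H2O,241.95,0,0,0,0,0,0,0,0,0,0,0,0,0,1,2,0,0,0
CoCl2.6H2O,CoCl2·6H2O,237.93,0,0,0,0,0,0,0,2,0,0,0,0,0,0,0,1,0,0
FeSO4.7H2O,FeSO4·7H2O,278.01,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0
Na2EDTA.2H2O,Na2EDTA·2H2O,372.24,0,0,0,0,0,0,0,0,0,0,0,0,0,0,2,0,0,1
(NH4)2SO4,(NH4)2SO4,132.14,2,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0
Ca(NO3)2.4H2O,Ca(NO3)2·4H2O,236.15,0,2,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
NaH2PO4.H2O,NaH2PO4·H2O,137.99,0,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0
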