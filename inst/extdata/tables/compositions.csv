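material,element,mass_fraction
air,N,0.755268
air,O,0.231781
air,Ar,0.012827
air,C,0.000124
glass,Na,0.1020
glass,Ca,0.0510
glass,Si,0.2480
glass,O,0.5990
LW concrete,H,0.01
LW concrete,C,0.001
LW concrete,O,0.529107
LW concrete,Na,0.016
LW concrete,Mg,0.002
LW concrete,Al,0.033872
LW concrete,Si,0.337021
LW concrete,K,0.013
LW concrete,Ca,0.044
LW concrete,Fe,0.014
NW concrete,H,0.01
NW concrete,C,0.001
NW concrete,O,0.529107
NW concrete,Na,0.016
NW concrete,Mg,0.002
NW concrete,Al,0.033872
NW concrete,Si,0.337021
NW concrete,K,0.013
NW concrete,Ca,0.044
NW concrete,Fe,0.014
A514 steel,Fe,0.97
A514 steel,Mn,0.0095
A514 steel,Cr,0.0065
A514 steel,Si,0.006
A514 steel,Mo,0.0023
A514 steel,C,0.004675
A514 steel,Zr,0.001
A514 steel,B,0.000025
gypsum,H,0.0234
gypsum,O,0.55757
gypsum,S,0.186218
gypsum,Ca,0.23279
muscle,H,0.102
muscle,C,0.143
muscle,N,0.034
muscle,O,0.71
muscle,Na,0.001
muscle,P,0.002
muscle,S,0.003
muscle,Cl,0.001
muscle,K,0.004
lead,Pb,1.0
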