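name,density_g_cm3,source
air,0.001205,table
glass,2.5,table
LW concrete,1.6,table
NW concrete,2.3,table
A514 steel,7.85,table
gypsum,2.33,table
muscle,1.05,table
lead,11.35,added
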