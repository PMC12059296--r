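name,half_life_value,half_life_unit,decay_mode,gamma_constant_R_cm2_per_mCi_h,f_factor_cGy_per_R
Tc-99m,6.02,h,Isomeric transition gamma emission 89.07%,0.795,0.959
I-131,8.02,d,beta-,2.2,0.963
Lu-177,6.65,d,beta-,0.181,0.957
F-18,109.8,min,beta+ EC,5.7,0.876
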