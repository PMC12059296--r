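nuclide,energy_keV,yield
Tc-99m,140,0.8907
I-131,364,0.812
I-131,637,0.0726
Lu-177,113,0.06
Lu-177,208,0.11
F-18,511,1.94
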