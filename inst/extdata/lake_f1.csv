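group,TChl_c,Peri,Fuco,Neo,Viola,Allo,Lut,Zea,Echin,TChl_b,TChl_a
Diatoms,0.021,0,0.039,0,0,0,0,0.005,0,0,1
Chlorophyceae,0,0,0,0.03,0.025,0,0.099,0.001,0,0.172,1
Cyanophytes,0,0,0,0,0,0,0,0.284,0.055,0,1
Chrysophytes,0,0,0.207,0,0.094,0,0,0.001,0,0,1
Dinophyceae,0,0.334,0,0,0,0,0,0,0,0,1
Cryptophytes,0,0,0,0,0,0.143,0,0,0,0,1
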