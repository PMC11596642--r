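group,TChl_c,Peri,Fuco,Neo,Viola,Allo,Lut,Zea,Echin,TChl_b,TChl_a
Diatoms,0.0190302727703936,0,0.0401365124682896,0,0,0,0,0.00412357254093513,0,0,1
Chlorophyceae,0,0,0,0.0264201831724495,0.028983896849677,0,0.104112916138396,0.00088238982995972,0,0.190565089695901,1
Cyanophytes,0,0,0,0,0,0,0,0.247256847087294,0.0524502818007022,0,1
Chrysophytes,0,0,0.240799605011567,0,0.110719790099561,0,0,0.00107480913866311,0,0,1
Dinophyceae,0,0.316915752991475,0,0,0,0,0,0,0,0,1
Cryptophytes,0,0,0,0,0,0.152197633730248,0,0,0,0,1
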