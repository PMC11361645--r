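variant,nucleotide,k_on_per_uM_s,k_off_per_s,kcat_per_s,kd_printed_uM
WT,GDP,0.044,0.012,0.0015,0.267
WT,GppNHp,0.029,0.001,0.0015,0.029
T30N,GDP,0.048,0.149,0.0012,3.091
T30N,GppNHp,NA,0.004,0.0012,NA
Q70L,GDP,0.401,0.025,0.0007,0.061
Q70L,GppNHp,0.222,0.006,0.0007,0.026
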