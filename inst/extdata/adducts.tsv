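adduct	mass_shift	charge
[M+H]+	1.00727646688	1
[M+Na]+	22.98922070	1
[M+NH4]+	18.03382555	1
[M-H]-	-1.00727646688	-1
[M+HCOO]-	44.99820285	-1
[M+CH3COO]-	59.01385292	-1
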