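"element","r_cov"
"H",0.32
"He",0.46
"C",0.75
"N",0.71
"O",0.63
"F",0.64
"Mg",1.39
"P",1.11
"S",1.03
"Cl",0.99
"Zn",1.18
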