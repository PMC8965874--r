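"element","q"
"H",2
"He",1.35
"C",3.05
"N",2.71
"O",2.42
"F",2.21
"Mg",5.52
"P",4.52
"S",4.23
"Cl",3.81
"Zn",5.01
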