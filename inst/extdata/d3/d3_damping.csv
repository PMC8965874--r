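"functional","s6","s8","a1","a2"
"b3lyp",1,1.9889,0.3981,4.4211
"pbe0",1,1.2177,0.4145,4.8593
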