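magnification,numerical_aperture
1,0.033
2,0.065
4,0.125
10,0.286
20,0.5
40,0.8
60,1
100,1.25
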