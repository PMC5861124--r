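pitch_over_circumf,phi,p,a,b,c
0,147.16,10.48,1.35,0.017,-0.112
-0.25,146.53,10.59,1.30,0.018,-0.109
-0.5,146.13,10.40,1.24,0.021,-0.116
-0.75,145.33,10.58,1.19,0.018,-0.114
-1,144.74,10.62,1.01,0.021,-0.107
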