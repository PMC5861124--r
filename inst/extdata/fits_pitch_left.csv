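pitch_over_circumf,phi,p,a,b,c
0,147.16,10.48,1.35,0.017,-0.112
0.25,147.79,10.52,1.30,0.019,-0.110
0.5,148.33,10.57,1.24,0.020,-0.108
0.75,149.02,10.52,1.18,0.020,-0.107
1,149.65,10.43,1.07,0.022,-0.112
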