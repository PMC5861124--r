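bend_deg,phi,p,a,b,c
15,147.24,10.42,-0.74,0.036,-0.113
30,147.12,10.55,-0.30,0.031,-0.112
45,147.33,10.39,0.18,0.030,-0.121
60,147.20,10.43,0.63,0.025,-0.113
75,147.22,10.43,1.02,0.021,-0.117
90,147.16,10.48,1.35,0.017,-0.112
105,147.16,10.49,1.64,0.016,-0.111
120,147.19,10.48,1.92,0.009,-0.112
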