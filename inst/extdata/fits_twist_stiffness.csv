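K3_over_K1,phi,p,a,b,c
0.5,147.45,10.58,1.03,0.016,-0.036
0.7,147.37,10.58,1.17,0.017,-0.053
0.9,147.37,10.49,1.21,0.017,-0.069
1.1,147.11,10.68,1.28,0.018,-0.081
1.3,147.30,10.36,1.30,0.015,-0.101
1.5,147.16,10.48,1.35,0.017,-0.112
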