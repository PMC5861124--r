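beta,phi,p,a,b,c
0.87,147.17,10.59,1.89,0.015,-0.093
0.945,147.23,10.43,1.65,0.015,-0.104
1,147.16,10.48,1.35,0.017,-0.112
1.065,147.08,10.53,1.04,0.024,-0.121
1.13,147.16,10.50,0.75,0.023,-0.121
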