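helical_repeat,phi,p,a,b,c
10.3,144.40,10.33,1.15,0.025,-0.112
10.4,145.68,10.48,1.32,0.014,-0.112
10.5,147.16,10.48,1.35,0.017,-0.112
10.6,148.60,10.59,1.28,0.022,-0.102
10.7,150.07,10.59,1.35,0.015,-0.102
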