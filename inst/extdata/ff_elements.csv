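element,rmin,eps,sigma_solv
C,2.000,0.080,0.012
N,1.850,0.200,-0.018
O,1.700,0.120,-0.018
S,2.000,0.450,0.012
H,0.2245,0.046,0.000
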