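pair,dH,dS
G.U,0.0,1.677
G.G,0.0,0.671
A.G,0.0,-1.342
U.U,0.0,-2.013
C.U,0.0,-3.019
A.A,0.0,-3.354
A.C,0.0,-3.689
C.C,0.0,-4.025
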