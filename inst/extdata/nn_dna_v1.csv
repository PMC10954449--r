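context,dH,dS,kind
AA/TT,-7.9,-22.2,stack
AT/TA,-7.2,-20.4,stack
TA/AT,-7.2,-21.3,stack
CA/GT,-8.5,-22.7,stack
GT/CA,-8.4,-22.4,stack
CT/GA,-7.8,-21.0,stack
GA/CT,-8.2,-22.2,stack
CG/GC,-10.6,-27.2,stack
GC/CG,-9.8,-24.4,stack
GG/CC,-8.0,-19.9,stack
init_A/T,2.3,4.1,init
init_G/C,0.1,-2.8,init
sym,0.0,-1.4,sym
bulge1,0.0,-13.416,loop
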