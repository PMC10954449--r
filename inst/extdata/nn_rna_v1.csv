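context,dH,dS,kind
AA/UU,-6.82,-19.0,stack
AU/UA,-9.38,-26.7,stack
UA/AU,-7.69,-20.5,stack
CA/GU,-10.44,-26.9,stack
GU/CA,-11.40,-29.5,stack
CU/GA,-10.48,-27.1,stack
GA/CU,-12.44,-32.5,stack
CG/GC,-10.64,-26.7,stack
GC/CG,-14.88,-36.9,stack
GG/CC,-13.39,-32.7,stack
init,3.61,-1.5,init0
init_A/U,3.72,10.5,init
init_G/C,0.0,0.0,init
sym,0.0,-1.4,sym
bulge1,0.0,-12.745,loop
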