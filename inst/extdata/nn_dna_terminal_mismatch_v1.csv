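context,dH,dS
AA/TA,-3.1,-7.8
AA/TC,-1.6,-4.0
AA/TG,-1.9,-4.4
AC/TA,-1.8,-3.8
AC/TC,-0.1,0.5
AC/TT,-0.9,-1.7
AG/TA,-2.5,-5.9
AG/TG,-1.1,-2.1
AG/TT,-3.2,-8.7
AT/TC,-2.3,-6.3
AT/TG,-3.5,-9.4
AT/TT,-2.4,-6.5
CA/GA,-4.3,-10.7
CA/GC,-2.6,-5.9
CA/GG,-3.9,-9.6
CC/GA,-2.7,-6.0
CC/GC,-2.1,-5.1
CC/GT,-3.2,-8.0
CG/GA,-6.0,-15.5
CG/GG,-3.8,-9.5
CG/GT,-3.8,-9.0
CT/GC,-3.9,-10.6
CT/GG,-6.6,-18.7
CT/GT,-6.1,-16.9
GA/CA,-8.0,-22.5
GA/CC,-5.0,-13.8
GA/CG,-4.3,-11.1
GC/CA,-3.2,-7.1
GC/CC,-3.9,-10.6
GC/CT,-4.9,-13.5
GG/CA,-4.6,-11.4
GG/CG,-0.7,-19.2
GG/CT,-5.7,-15.9
GT/CC,-3.0,-7.8
GT/CG,-5.9,-16.1
GT/CT,-7.4,-21.2
TA/AA,-2.5,-6.3
TA/AC,-2.3,-5.9
TA/AG,-2.0,-4.7
TC/AA,-2.7,-7.0
TC/AC,-0.7,-1.3
TC/AT,-2.5,-6.3
TG/AA,-2.4,-5.8
TG/AG,-1.1,-2.7
TG/AT,-3.9,-10.5
TT/AC,-0.7,-1.2
TT/AG,-3.6,-9.8
TT/AT,-3.2,-8.9
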