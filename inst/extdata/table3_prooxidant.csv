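complex_label,stoichiometry,motif,reductant,delta_e,delta_g,lamda,delta_g_act,k,direction
Cu(H2O)4^2+,free,NA,superoxide,1.6,-27.8,38.7,0.8,3.76e9,ref
Cu(H2O)4^2+,free,NA,ascorbate,22.8,-3.1,33.4,6.9,5.70e7,ref
[Cu(H3Glg)(H2O)2]^2+,mono,C3C4,superoxide,-1.3,-28.3,35.7,0.4,4.07e9,up
[Cu(H3Glg)(H2O)2]^2+,mono,C3C4,ascorbate,19.9,-3.7,29.8,5.7,3.63e8,up
[Cu(H3Glg)(H2O)2]^2+,mono,C4C5,superoxide,-1.6,-27.8,34.8,0.4,4.05e9,up
[Cu(H3Glg)(H2O)2]^2+,mono,C4C5,ascorbate,19.6,-3.2,28.9,5.7,3.47e8,up
[Cu(H2Glg)(H2O)2]^+,mono,C3C4,superoxide,-0.8,-26.3,34.3,0.5,3.98e9,up
[Cu(H2Glg)(H2O)2]^+,mono,C3C4,ascorbate,20.4,-1.7,28.5,6.3,1.45e8,up
[Cu(H2Glg)(H2O)2]^+,mono,C4C5,superoxide,1.9,-25.2,35.8,0.8,4.06e9,up
[Cu(H2Glg)(H2O)2]^+,mono,C4C5,ascorbate,23.2,-0.6,29.9,7.2,3.29e7,down
[Cu(HGlg)(H2O)2],mono,C3C4,superoxide,15.3,-18.5,42.5,3.4,3.33e9,down
[Cu(HGlg)(H2O)2],mono,C3C4,ascorbate,36.5,6.2,36.7,12.5,4.19e3,down
[Cu(H3Glg)2]^2+,bis,C3C4,superoxide,-6.3,-26.8,29.0,0.0,4.35e9,up
[Cu(H3Glg)2]^2+,bis,C3C4,ascorbate,14.9,-2.1,22.8,4.7,1.43e9,up
[Cu(H3Glg)2]^2+,bis,C4C5,superoxide,-3.8,-26.2,30.9,0.2,4.28e9,up
[Cu(H3Glg)2]^2+,bis,C4C5,ascorbate,17.4,-1.5,24.8,5.5,5.34e8,up
[Cu(H2Glg)2],bis,C4C5,superoxide,2.2,-19.1,29.9,1.0,4.31e9,up
[Cu(H2Glg)2],bis,C4C5,ascorbate,23.4,5.5,23.7,9.0,1.51e6,down
[Cu(HGlg)2]^2-,bis,C3C4,superoxide,26.8,-1.7,37.1,8.4,4.12e6,down
[Cu(HGlg)2]^2-,bis,C3C4,ascorbate,48.0,22.9,31.0,23.4,4.15e-5,down
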