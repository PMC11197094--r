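complex_label,stoichiometry,motif,delta_e,delta_g,lamda,delta_g_act,k
[Cu(H3Glg)(H2O)2]^2+,mono,C3C4,15.2,10.0,15.1,10.5,1.32e5
[Cu(H3Glg)(H2O)2]^2+,mono,C4C5,10.7,7.0,13.6,7.8,1.18e7
[Cu(H2Glg)(H2O)2]^+,mono,C3C4,-3.8,-5.1,11.2,0.8,4.15e9
[Cu(H2Glg)(H2O)2]^+,mono,C4C5,-5.2,-7.1,11.8,0.5,4.27e9
[Cu(HGlg)(H2O)2],mono,C3C4,-14.0,-16.8,12.7,0.3,4.16e9
[Cu(H3Glg)2]^2+,bis,C3C4,18.4,19.0,9.3,21.5,1.07e-3
[Cu(H3Glg)2]^2+,bis,C4C5,14.4,15.0,9.3,15.8,1.61e1
[Cu(H2Glg)2],bis,C4C5,-1.1,-0.6,9.4,2.1,4.49e9
[Cu(HGlg)2]^2-,bis,C3C4,-13.6,-12.8,9.1,0.4,4.57e9
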