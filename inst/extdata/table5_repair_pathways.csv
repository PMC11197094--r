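target,form,species,site,delta_g,delta_g_act,k,note
LM,radical,H3Glg,C3,11.4,NA,NA,
LM,radical,H3Glg,C5,24.3,NA,NA,
LM,radical,H3Glg,C7,20.8,NA,NA,
2dG,radical,H3Glg,C3,-10.9,19.5,1.70e1,
2dG,radical,H3Glg,C5,-1.1,28.0,1.33e-4,
2dG,radical,H3Glg,C7,-0.2,22.9,1.18e-2,
2dG,radical,H2Glg-,C3,-14.2,18.3,1.56e2,
2dG,radical,H2Glg-,C5,-3.0,27.3,5.62e-4,
2dG,radical,HGlg2-,C5,-12.3,27.4,2.36e-4,
2dG,radical-cation,H3Glg,SET,3.2,6.8,6.15e7,
2dG,radical-cation,H2Glg-,SET,-11.7,0.3,3.71e9,
2dG,radical-cation,HGlg2-,SET,-31.9,2.2,3.62e9,
NF-Cys,radical,H3Glg,C3,-0.7,19.3,9.69e0,
NF-Cys,radical,H3Glg,C5,9.0,26.7,2.07e-3,
NF-Cys,radical,H3Glg,C7,9.9,30.8,3.00e-10,
NF-Cys,radical,H2Glg-,C3,-4.1,17.5,4.41e1,
NF-Cys,radical,H2Glg-,C5,7.2,18.7,5.48e-1,
NF-Cys,radical,HGlg2-,C5,-2.1,5.1,7.52e8,
NF-His,radical,H3Glg,C3,-5.9,22.3,1.15e-1,
NF-His,radical,H3Glg,C5,3.8,30.5,3.02e-7,
NF-His,radical,H3Glg,C7,4.7,30.1,1.19e-7,
NF-His,radical,H2Glg-,C3,-9.3,20.9,1.31e1,
NF-His,radical,H2Glg-,C5,2.0,28.9,5.36e-6,
NF-His,radical,HGlg2-,C5,-7.3,19.4,9.29e0,
NF-Leu,radical,H3Glg,C3,-9.2,17.9,4.18e1,
NF-Leu,radical,H3Glg,C5,0.5,26.0,8.90e-5,
NF-Leu,radical,H3Glg,C7,1.4,24.4,1.75e-4,
NF-Leu,radical,H2Glg-,C3,-12.6,17.7,9.15e1,
NF-Leu,radical,H2Glg-,C5,-1.3,29.7,7.11e-7,
NF-Leu,radical,HGlg2-,C5,-10.6,26.4,4.99e-4,
NF-Met,radical,H3Glg,C3,-7.9,16.3,9.61e1,
NF-Met,radical,H3Glg,C5,1.8,31.0,3.36e-9,
NF-Met,radical,H3Glg,C7,2.7,18.5,7.06e-1,
NF-Met,radical,H2Glg-,C3,-11.3,16.6,7.29e1,
NF-Met,radical,H2Glg-,C5,0.0,31.3,9.81e-8,
NF-Met,radical,HGlg2-,C5,-9.4,31.8,3.29e-7,
NF-Trp,radical-cation,H3Glg,SET,11.1,11.8,1.35e4,
NF-Trp,radical-cation,H2Glg-,SET,-3.9,1.9,3.66e9,
NF-Trp,radical-cation,HGlg2-,SET,-23.9,0.7,3.71e9,
NF-Tyr,radical,H3Glg,C3,-2.5,15.1,3.76e3,
NF-Tyr,radical,H3Glg,C5,7.2,23.8,7.68e-4,
NF-Tyr,radical,H3Glg,C7,8.2,18.7,1.45e-1,
NF-Tyr,radical,H2Glg-,C3,-5.9,16.3,2.52e2,
NF-Tyr,radical,H2Glg-,C5,5.4,21.0,8.78e-2,
NF-Tyr,radical,HGlg2-,C5,-3.9,2.5,1.77e9,tst_not_converged
NF-Tyr,radical-cation,H3Glg,SET,1.3,5.5,5.18e8,
NF-Tyr,radical-cation,H2Glg-,SET,-13.6,0.0,3.71e9,
NF-Tyr,radical-cation,HGlg2-,SET,-33.6,3.6,2.92e9,
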