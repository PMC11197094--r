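species,mechanism,site,medium,delta_g_act,k,gamma
H3GlgPET,fHAT,C3,lipid,16.7,3.77e3,99.89
H3GlgPET,fHAT,C7,lipid,19.8,1.73e0,0.05
H3GlgPET,RAF,C2,lipid,17.8,8.04e-1,0.02
H3GlgPET,RAF,C3,lipid,17.3,1.75e0,0.05
H3Glg,fHAT,C3,water,15.4,6.42e3,99.30
H3Glg,fHAT,C5,water,24.1,1.28e-1,0.00
H3Glg,fHAT,C7,water,22.0,6.95e-1,0.01
H3Glg,RAF,C2,water,15.6,3.33e1,0.52
H3Glg,RAF,C3,water,16.2,1.13e1,0.18
H3Glg,SET,SET,water,34.1,5.89e-13,0.00
H2Glg-,fHAT,C3,water,13.8,5.04e4,98.64
H2Glg-,fHAT,C5,water,22.3,2.88e0,0.01
H2Glg-,RAF,C2,water,14.2,3.27e2,0.64
H2Glg-,RAF,C3,water,14.1,3.64e2,0.71
H2Glg-,SET,SET,water,19.1,6.51e-2,0.00
HGlg2-,fHAT,C5,water,22.4,1.08e1,0.00
HGlg2-,RAF,C2,water,2.3,2.50e9,51.68
HGlg2-,RAF,C3,water,3.5,1.83e9,37.92
HGlg2-,RAF,C4,water,5.9,2.74e8,5.68
HGlg2-,RAF,C8,water,12.3,6.59e3,0.00
HGlg2-,RAF,C2',water,15.0,7.11e1,0.00
HGlg2-,RAF,C4',water,14.0,4.38e2,0.00
HGlg2-,RAF,C6',water,14.6,1.42e2,0.00
HGlg2-,SET,SET,water,6.0,2.28e8,4.72
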