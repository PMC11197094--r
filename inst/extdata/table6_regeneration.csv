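species,site_or_set,delta_g,delta_g_act,k,delta_g_protonation
H3Glg,C3,-20.1,1.3,4.00e9,-32.6
H3Glg,C5,-29.6,0.8,3.96e9,-32.8
H3Glg,C7,-34.2,0.7,3.98e9,-29.2
H3Glg,SET,-49.2,3.6,3.98e9,NA
H2Glg-,C3,-13.9,0.7,3.45e9,-35.1
H2Glg-,C5,-21.3,0.1,3.83e9,-39.1
H2Glg-,SET,-34.2,1.0,3.98e9,NA
HGlg2-,C5,-7.5,3.6,3.09e9,-43.8
HGlg2-,SET,-14.2,1.6,3.98e9,NA
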