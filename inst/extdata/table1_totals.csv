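species,medium,k_total,k_corrected
H3GlgPET,lipid,3.77e3,NA
H3Glg,water,6.46e3,8.81e0
H2Glg-,water,5.11e4,5.78e1
HGlg2-,water,4.83e9,6.21e4
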