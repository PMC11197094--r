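target,form,species,k_total,k_overall,note
2dG,radical,H3Glg,1.70e1,9.23e0,
2dG,radical,H2Glg-,1.56e2,7.04e1,
2dG,radical,HGlg2-,2.36e-4,1.21e-6,
2dG,radical-cation,H3Glg,6.15e7,3.34e7,
2dG,radical-cation,H2Glg-,3.71e9,1.67e9,
2dG,radical-cation,HGlg2-,3.62e9,1.86e7,
NF-Cys,radical,H3Glg,9.69e0,5.27e0,
NF-Cys,radical,H2Glg-,4.46e1,2.01e1,
NF-Cys,radical,HGlg2-,7.52e8,3.86e6,
NF-His,radical,H3Glg,1.15e-1,6.25e-2,
NF-His,radical,H2Glg-,1.31e0,5.93e-1,printed_total_mismatches_pathway
NF-His,radical,HGlg2-,9.29e0,4.72e-2,printed_ratio_outlier
NF-Leu,radical,H3Glg,4.18e1,2.27e1,
NF-Leu,radical,H2Glg-,9.15e1,4.13e1,
NF-Leu,radical,HGlg2-,4.99e-4,2.56e-6,
NF-Met,radical,H3Glg,9.68e1,5.26e1,
NF-Met,radical,H2Glg-,7.29e1,3.29e1,
NF-Met,radical,HGlg2-,3.29e-7,1.69e-9,
NF-Trp,radical-cation,H3Glg,1.35e4,7.34e3,
NF-Trp,radical-cation,H2Glg-,3.66e9,1.65e9,
NF-Trp,radical-cation,HGlg2-,3.71e9,1.90e7,
NF-Tyr,radical,H3Glg,3.76e3,2.04e3,
NF-Tyr,radical,H2Glg-,2.52e2,1.02e2,printed_ratio_outlier
NF-Tyr,radical,HGlg2-,1.77e9,9.05e6,tst_not_converged
NF-Tyr,radical-cation,H3Glg,5.18e8,2.81e8,
NF-Tyr,radical-cation,H2Glg-,3.71e9,1.67e9,
NF-Tyr,radical-cation,HGlg2-,2.92e9,1.50e7,
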