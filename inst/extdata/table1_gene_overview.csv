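gene_id,aliases,microarray_fc,microarray_call,qpcr_fc,qpcr_call,western_fc,western_call,rna_protein_r,correlation_sign
CENPA,,38.5,UP,39.2,UP,8.0,UP,0.76,1
DLG7,DLGAP5;HURP,36.0,UP,24,UP,41,UP,0.7,1
PBK,TOPK,40.7,UP,38.1,UP,24.6,UP,0.74,1
FILIP1L,,16.1,UP,4.5,NS,31.7,UP,0.73,1
CDC6,,26.2,UP,9.2,UP,8.8,UP,0.66,1
NOL4,,13.5,UP,30.5,UP,7.1,UP,0.7,1
MCC,,12.4,UP,8.1,UP,0.3,DR,0.42,-1
KIF15,,13,UP,62.7,UP,4.7,UP,0.73,1
MPP6,,10.6,UP,9.8,UP,4.6,UP,0.8,1
KIF18A,,12.8,UP,11,UP,22.4,UP,0.89,1
EZH2,,13.7,UP,35.3,UP,17.1,UP,0.92,1
DEPDC1,,12.2,UP,15.7,UP,49.9,UP,0.52,1
RAPGEF4,,9.1,UP,33.4,UP,0.2,DR,0.59,-1
HMMR,RHAMM;CD168,10.0,UP,25,UP,7.7,UP,0.86,1
ATXN7L4,ATXN7L1,7.4,UP,3.2,UP,0.9,DR,0.4,1
P2RY5,LPAR6,5.7,UP,0.5,NS,0.1,DR,0.52,1
FAM118A,,3.2,UP,0.3,DR,7.3,UP,0.61,1
RHBDD1,,3.3,UP,1.2,NS,2.3,UP,0.05,-1
FNDC3B,,3.3,UP,0.8,NS,17.5,UP,0.63,1
MDM1,,3.4,UP,3.4,UP,30.4,UP,0.88,1
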