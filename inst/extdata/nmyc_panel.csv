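name,sequence,offset,constraint_i,constraint_j,state,ic50_uM,ic50_sd_uM,mre222,mre222_sd,helicity_pct
N-Myc_61-89,Ac-LSPSRGFAEHSSEPPSWVTEMLLENELWG-NH2,61,NA,NA,NA,42,4,-2059,64,6
N-Myc_73-89,Ac-EPPSWVTEMLLENELWG-NH2,73,NA,NA,NA,179,19,-4079,71,13
N-Myc_76-89,Ac-SWVTEMLLENELWG-NH2,76,NA,NA,NA,215,11,-4342,142,14
N-Myc_73-94,Ac-EPPSWVTEMLLENELWGSPAEE-NH2,73,NA,NA,NA,199,13,-4235,181,13
N-Myc_73-97,Ac-EPPSWVTEMLLENELWGSPAEEDAF-NH2,73,NA,NA,NA,79,4,-4886,55,14
N-Myc_73-89-E73pS,Ac-pSPPSWVTEMLLENELWG-NH2,73,NA,NA,NA,140,18,-5394,235,16
N-Myc_73-89-E73S,Ac-SPPSWVTEMLLENELWG-NH2,73,NA,NA,NA,217,13,-5541,66,17
N-Myc_73-94-N85C/G89C-red,Ac-EPPSWVTEMLLECELWCSPAEE-NH2,73,85,89,red,123,10,-4383,64,13
N-Myc_73-94-N85C/G89C-ox,Ac-EPPSWVTEMLLECELWCSPAEE-NH2,73,85,89,ox,130,9,-5255,217,15
N-Myc_73-94-N85C/G89C-mal,Ac-EPPSWVTEMLLECELWCSPAEE-NH2,73,85,89,mal,49,5,-7223,168,21
N-Myc_73-94-E86C/S90C-red,Ac-EPPSWVTEMLLENCLWGCPAEE-NH2,73,86,90,red,203,4,-6397,64,18
N-Myc_73-94-E86C/S90C-ox,Ac-EPPSWVTEMLLENCLWGCPAEE-NH2,73,86,90,ox,172,23,-7454,130,21
N-Myc_73-94-E86C/S90C-mal,Ac-EPPSWVTEMLLENCLWGCPAEE-NH2,73,86,90,mal,111,18,-5715,64,17
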