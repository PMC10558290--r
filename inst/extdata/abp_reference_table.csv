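name,common_name,mw,abundance,abundance_sd,n_blots,cellular_conc,cellular_conc_sd,molecules_per_cell,cytosolic_fraction,cytosolic_fraction_sd,cytosolic_conc,cytosolic_conc_sd,method,binds_f_actin,binds_g_actin,oligomer_n
Act1,Actin,41.8,7.99,1.48,11,13.2,2.44,2.17e5,NA,NA,NA,NA,western,FALSE,FALSE,1
Tpm1,Tropomyosin,23.5,4.22,1.08,6,12.4,3.16,2.03e5,0.89,0.08,11,0.98,western,TRUE,FALSE,1
Pfy1,Profilin,13.6,1.54,0.27,NA,7.73,1.38,1.27e5,NA,NA,NA,NA,gfp,FALSE,TRUE,1
Cof1,Cofilin,16,1.76,0.78,3,7.58,3.36,1.25e5,NA,NA,NA,NA,western,TRUE,TRUE,1
Abp1,Actin-binding protein 1,65.6,4.91,0.79,2,5.15,0.83,8.47e4,0.61,0.11,3.2,0.60,western,TRUE,FALSE,1
Srv2,Cyclase-associated protein,57.6,2.41,0.36,5,2.88,0.43,4.74e4,0.78,0.09,2.2,0.26,western,TRUE,TRUE,6
Abp140,Actin binding protein,71.4,2.94,NA,NA,2.83,0.60,4.65e4,0.87,0.08,2.5,0.23,gfp,TRUE,FALSE,1
Tpm2,Tropomyosin,19.1,0.70,NA,NA,2.54,NA,4.17e4,0.91,0.08,2.3,0.20,ratio,TRUE,FALSE,1
Aip1,Actin-interacting protein 1,67.4,1.81,0.02,2,1.85,0.02,2.40e4,0.82,0.07,1.5,0.13,western,TRUE,FALSE,1
Cap1/2,Capping protein (alpha/beta dimer),64.3,1.43,0.53,7,1.46,0.54,5.12e4,0.67,0.08,0.9,0.15,western,TRUE,FALSE,2
Crn1,Coronin,72.6,1.48,0.28,6,1.40,0.27,2.31e4,0.63,0.11,0.9,0.15,western,TRUE,FALSE,1
Sac6,Fimbrin,71.8,1.26,0.02,2,1.21,0.02,1.99e4,0.80,0.08,1.0,0.10,western,TRUE,FALSE,1
Twf1,Twinfilin,37.1,0.59,0.19,8,1.10,0.35,1.80e4,0.71,0.12,0.8,0.13,western,TRUE,TRUE,1
Arp2,Actin-related protein 2,44.1,0.63,0.20,4,0.98,0.31,1.62e4,0.81,0.07,0.8,0.07,western,TRUE,FALSE,1
Scp1,Calponin/transgelin,22.8,0.28,0.05,3,0.85,0.15,1.39e4,0.74,0.13,0.6,0.11,western,TRUE,FALSE,1
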