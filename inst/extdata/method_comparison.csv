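name,western,gfp,mass_spec
Act1,13.2,NA,14.8
Abp1,5.15,5.55,NA
Srv2,2.88,NA,2.69
Cap1/2,1.46,1.62,NA
Crn1,1.40,1.56,NA
Sac6,1.21,7.71,1.40
Twf1,1.10,0.53,0.65
Scp1,0.85,NA,1.02
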