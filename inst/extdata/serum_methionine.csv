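# thiosulfate_mM: 0
# yeast_extract_g_L: 1
# phases: t0=0 t1=0 t2=14.5 t3=22
# co2_mode: acetate_stoichiometric
# label: methionine
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,5.1,0,0,0,0,NA,0,0
14.5,217.7,11.9,1.1,17.3,30,NA,0,0
22,227.8,18.3,3.1,26.5,53.3,NA,0,0
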