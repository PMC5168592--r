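# thiosulfate_mM: 0
# yeast_extract_g_L: 1
# phases: t0=0 t1=0 t2=14.5 t3=22
# co2_mode: acetate_stoichiometric
# label: S0
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,5.9,0,0,0,0,NA,0,0
14.5,191.8,11,1.3,16.3,28,NA,0,0
22,158.2,16.6,3.4,23.8,46.1,NA,0,0
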