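# thiosulfate_mM: 0
# yeast_extract_g_L: 1
# phases: t0=0 t1=4.4 t2=41.7 t3=48.5
# co2_mode: measured
# label: pH2 606.9 mbar
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,18.9,0,0,0,NA,0,0,0
4.4,23.9,1,0,0,NA,0.3,0,0
41.7,96.4,11.9,8.9,12,NA,11.1,0,0
48.5,96.3,13.4,11,13,NA,12.2,0,0
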