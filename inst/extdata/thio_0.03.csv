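# thiosulfate_mM: 0.03
# yeast_extract_g_L: 1
# phases: t0=0 t1=6.7 t2=24.1 t3=27.5
# co2_mode: measured
# label: thiosulfate 0.03 mmol/L
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,23.6,0,0,0,0,0,0,0
6.7,32.1,0,0,0,0.3,0.2,0,0
24.1,265,25.2,6.8,27.5,53.5,27.3,0,0
27.5,264.1,28,8.2,30.6,57.9,29.7,0,0
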