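# thiosulfate_mM: 0.06
# yeast_extract_g_L: 1
# phases: t0=0 t1=1.8 t2=20.4 t3=22.3
# co2_mode: measured
# label: thiosulfate 0.06 mmol/L
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,26.1,0,0,0,0,0,0,0
1.8,33.7,0.7,0,0.1,0.3,0.1,0,0
20.4,353.5,38.2,18,37.7,73.2,35.7,0,0
22.3,352.3,38.5,18.1,38.2,73.3,35.8,0,0
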