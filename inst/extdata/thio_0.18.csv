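# thiosulfate_mM: 0.18
# yeast_extract_g_L: 1
# phases: t0=0 t1=1.2 t2=16.8 t3=17
# co2_mode: measured
# label: thiosulfate 0.18 mmol/L
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,25.3,0,0,0,0,0,0,0
1.2,32.7,0.3,0,0,0.4,0.4,0,0
16.8,428.8,45,23.3,44.5,86.7,44.6,0,0
17,418,45.4,23.4,45,86.9,44.7,0,0
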