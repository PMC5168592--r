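# thiosulfate_mM: 0.24
# yeast_extract_g_L: 1
# phases: t0=0 t1=2.1 t2=17 t3=22.8
# co2_mode: measured
# label: thiosulfate 0.24 mmol/L
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,27.5,0,0,0,0,0,0,0
2.1,33.8,0.9,0,0,0.5,0.2,0,0
17,423.9,41.7,22.5,43.4,84,40,3.8,2.9
22.8,422.4,43.8,26.4,46.1,88.6,42.2,3.8,2.9
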