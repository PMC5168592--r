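# thiosulfate_mM: 0.12
# yeast_extract_g_L: 1
# phases: t0=0 t1=3 t2=17.9 t3=23.2
# co2_mode: measured
# label: thiosulfate 0.12 mmol/L
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,24.4,0,0,0,0,0,0,0
3,34.1,1.1,0,0.8,0.3,0.3,0,0
17.9,404,42.4,15.9,47,90.5,44.2,3.8,3.6
23.2,396.6,45.7,15.4,52.4,99.7,51.9,3.8,3.6
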