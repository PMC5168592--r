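# thiosulfate_mM: 0.01
# yeast_extract_g_L: 1
# phases: t0=0 t1=3.1 t2=22.8 t3=23
# co2_mode: measured
# label: thiosulfate 0.01 mmol/L
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,16.8,0,0,0,0,0,0,0
3.1,22.8,2.1,0.1,0.2,0.4,0.2,0,0
22.8,178,19.8,10,16,30.7,15,0,0
23,177.4,20,10.2,16,31,15,0,0
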