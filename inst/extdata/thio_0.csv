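# thiosulfate_mM: 0
# yeast_extract_g_L: 1
# phases: t0=0 t1=4.8 t2=29.5 t3=30.6
# co2_mode: measured
# label: thiosulfate 0 mmol/L
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,19.3,0,0,0,0,0,0,0
4.8,31.8,1.3,0.2,0.5,0.3,0.2,0,0
29.5,127.6,16.4,4.9,11.8,23.2,11.1,1.39,4.7
30.6,119.8,17.7,5.4,12.8,25,11.9,1.39,4.7
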