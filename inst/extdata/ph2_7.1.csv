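# thiosulfate_mM: 0
# yeast_extract_g_L: 1
# phases: t0=0 t1=6.7 t2=41.7 t3=49.8
# co2_mode: measured
# label: pH2 7.1 mbar
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,14.8,0,0,0,0,0,0,0
6.7,17.5,0.3,0.1,0.6,0.4,0.4,0,0
41.7,127.5,18.5,8.9,23.6,44.5,22.5,0,0
49.8,122.5,19.8,10.5,25,46.4,23.3,0,0
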