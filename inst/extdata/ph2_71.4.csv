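# thiosulfate_mM: 0
# yeast_extract_g_L: 1
# phases: t0=0 t1=5.5 t2=40.4 t3=46.2
# co2_mode: measured
# label: pH2 71.4 mbar
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,14.7,0,0,0,0,0,0,0
5.5,19.1,0.5,0.2,0.7,1.4,0.3,0,0
40.4,123.6,18.1,8.8,22.5,43,20,0,0
46.2,118.2,19.7,11,24.6,48,21.8,0,0
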