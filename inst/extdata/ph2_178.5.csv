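# thiosulfate_mM: 0
# yeast_extract_g_L: 1
# phases: t0=0 t1=5.5 t2=38.2 t3=39
# co2_mode: measured
# label: pH2 178.5 mbar
time_h,cells_mg_L,glucose_consumed_mM,lactate_mM,acetate_mM,H2_mM,CO2_mM,alanine_mM,eps_glcEq_mM
0,12.7,0,0,0,0,0,0,0
5.5,22.7,0.2,0.1,0.2,0.6,0.3,0,0
38.2,129.8,16.9,9.2,19.9,39.3,19.2,0,0
39,127.3,17.2,9.4,20.1,40,19.5,0,0
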