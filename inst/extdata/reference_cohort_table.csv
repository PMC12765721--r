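measure,mean,sd,min,max
tmqhpli_tdp,2.59,0.93,1,5
tmqhpli_ddp,1.42,0.87,0,3
plani_tot_pct,45.80,18.21,4.03,96.33
plani_dark_pct,24.25,14.41,1.66,82.04
plani_light_pct,21.54,13.21,0.77,63.72
plani_volmap_pct,18.57,8.94,1.20,42.82
vpi_mm3,0.90,0.36,0.28,2.00
avpi_mm3_per_mm2,0.02,0.01,0.01,0.03
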