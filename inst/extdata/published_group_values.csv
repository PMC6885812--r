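measure,group,mean,sem,n
dead_pct,Sham,6.32,2.26,9
dead_pct,Hypoxia,49.55,3.72,9
dead_pct,Hypoxia+GDNF,11.12,3.21,9
synapse_density_per_100um2,Sham,498.6,87.7,3
synapse_density_per_100um2,Hypoxia,101.34,48.7,3
synapse_density_per_100um2,Hypoxia+GDNF,378.9,65.4,3
V4_gm,Sham,73.99,2.26,NA
V4_gm,Hypoxia,88.8,5.3,NA
V4_gm,Hypoxia+GDNF,50.2,7.9,NA
RCI,Sham,3.8,0.2,NA
RCI,Hypoxia,1.7,0.05,NA
RCI,Hypoxia+GDNF,4.5,0.4,NA
pct_active,Sham,61.09,5.01,NA
pct_active,Hypoxia,17.5,3.91,NA
pct_active,Hypoxia+GDNF,37.65,9.55,NA
freq_osc_per_min,Sham,2.06,0.12,NA
freq_osc_per_min,Hypoxia,0.81,0.09,NA
freq_osc_per_min,Hypoxia+GDNF,1.17,0.08,NA
duration_s,Sham,9.69,0.47,NA
duration_s,Hypoxia,13.96,1.12,NA
duration_s,Hypoxia+GDNF,13.33,0.42,NA
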