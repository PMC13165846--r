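parameter,unit,omc_mean,rmse,published_rel_rmse_pct
gait_cycle,s,1.05,0.167,15.9
step_length,m,0.68,0.0285,4.2
stride_length,m,1.36,0.0247,1.8
velocity,m/s,1.30,0.030,2.3
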