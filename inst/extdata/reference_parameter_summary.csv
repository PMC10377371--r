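parameter,mean,sd,min,max,ci_low,ci_high,cutoff_label,cutoff_source
t_half_s,4.07,5.85,0.03,87.67,3.45,4.70,<=10,regression
t_max_s,10.85,14.68,1.57,94.77,9.28,12.41,<=30,regression
perfusion_tr,0.43,0.16,0.01,1.00,0.41,0.44,<=0.8,coverage_interval
f_max_au,97.21,37.00,7.62,199.01,93.26,101.16,>=25,coverage_interval
slope_au_per_s,9.74,8.46,0.33,54.95,8.83,10.64,>=5,regression
nir_index,68.82,16.76,10.0,98.0,67.03,70.60,>=50,regression
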