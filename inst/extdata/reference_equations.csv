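parameter,model,n,intercept,beta_sto2,beta_sto2_sq,r_squared,cutoff_60,cutoff_65,cutoff_70,cutoff_75,cutoff_80
t_half_s,linear,340,26.351,-0.267,0,0.183,10.31,8.98,7.64,6.30,4.97
t_half_s,quadratic,340,82.801,-1.851,0.011,0.260,10.40,7.86,5.85,4.39,3.46
t_max_s,linear,340,76.287,-0.785,0,0.250,29.18,25.25,21.33,17.40,13.48
t_max_s,quadratic,340,252.715,-5.736,0.034,0.369,29.45,21.76,15.74,11.41,8.76
slope_au_per_s,linear,340,-2.236,0.144,0,0.025,6.38,7.10,7.82,8.54,9.26
slope_au_per_s,linear,335,-3.087,0.146,0,0.043,5.68,6.41,7.14,7.87,8.60
nir_index,linear,340,10.515,0.699,0,0.152,52.48,55.98,59.48,62.98,66.47
nir_index,linear,332,13.125,0.683,0,0.185,54.12,57.54,60.96,64.37,67.79
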