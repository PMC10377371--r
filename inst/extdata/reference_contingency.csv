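parameter,cutoff_label,direction,cutoff,tp,fp,fn,tn
t_half_s,<=10,le,10,319,5,10,6
t_max_s,<=30,le,30,322,1,7,10
perfusion_tr,<=0.8,le,0.8,322,8,7,3
f_max_au,>25,gt,25,314,11,15,0
slope_au_per_s,>=5,ge,5,234,0,95,11
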