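sex,term,value
F,log_age,2.32888
F,log_tc,1.20904
F,log_hdl,-0.70833
F,log_sbp_untreated,2.76157
F,log_sbp_treated,2.82263
F,smoking,0.52873
F,diabetes,0.69154
F,mean_lp,26.1931
F,s0_10y,0.95012
M,log_age,3.06117
M,log_tc,1.12370
M,log_hdl,-0.93263
M,log_sbp_untreated,1.93303
M,log_sbp_treated,1.99881
M,smoking,0.65451
M,diabetes,0.57367
M,mean_lp,23.9802
M,s0_10y,0.88936
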