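kidney,covariate,beta_median_std,s2s_median_sd_mm,reported_mm
left,ckd,-0.33,3.02,-1.0
right,ckd,-0.30,2.95,-0.89
left,t2d,0.20,3.02,0.6
right,t2d,0.20,2.95,0.59
left,hypertension,0.06,3.02,0.18
right,hypertension,0.07,2.95,0.15
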