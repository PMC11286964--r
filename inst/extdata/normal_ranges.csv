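variable,alpha,beta,extra_scale
m_protein,0,3,1
kappa_flc,3.3,19.4,0.2
hemoglobin,120,160,1
creatinine,60,110,1
calcium,2.1,2.6,1
albumin,35,50,1
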