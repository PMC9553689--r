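sample_id,methyl_butyrate,methyl_palmitate,methyl_stearate,methyl_oleate,methyl_linoleate,methyl_arachidate,methyl_gamma_linolenate,methyl_behenate,sfa_pct,pufa_pct
cnd,nd,6.341,3.022,22.887,43.003,nd,24.747,nd,9.364,67.750
pnt,0.391,17.529,1.761,23.455,50.366,2.006,0.923,3.567,25.254,51.289
ssm,nd,9.481,5.205,38.422,46.345,0.554,nd,nd,15.240,46.345
snf,nd,12.051,9.206,38.467,36.939,0.600,1.102,1.632,23.488,38.040
inc,nd,4.152,2.944,8.070,40.139,nd,44.301,0.395,7.491,84.440
bkb,nd,10.328,3.885,25.455,51.627,nd,8.704,nd,14.213,60.331
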