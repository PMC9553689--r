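sample_id,omega3_pct,omega6_pct,omega9_pct,sfa_pct,pufa_pct
cnd,23.310,42.046,22.480,12.164,65.356
pnt,nd,36.040,41.102,22.858,36.040
ssm,nd,43.591,37.489,18.920,43.591
snf,nd,58.752,21.712,19.536,58.752
inc,44.050,33.792,10.842,11.316,77.842
bkb,10.232,45.457,26.796,17.515,55.688
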