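sample_id,mean,sd
cnd,1.066,0.067
pnt,1.457,0.100
ssm,2.746,0.155
snf,1.888,0.101
inc,2.467,0.134
bkb,1.269,0.066
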