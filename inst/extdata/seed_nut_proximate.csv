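sample_id,nutrient,mean,sd
cnd,oil,60.956,1.279
cnd,moisture,4.329,0.419
cnd,ash,1.720,0.676
cnd,protein,20.521,2.273
cnd,carbohydrate,12.438,2.518
pnt,oil,39.733,1.197
pnt,moisture,7.146,0.483
pnt,ash,2.370,0.124
pnt,protein,15.586,0.986
pnt,carbohydrate,35.186,1.550
ssm,oil,56.288,1.791
ssm,moisture,3.550,0.402
ssm,ash,2.726,0.138
ssm,protein,21.543,3.341
ssm,carbohydrate,15.945,3.342
snf,oil,44.390,1.542
snf,moisture,3.086,0.305
snf,ash,4.440,0.067
snf,protein,28.549,3.702
snf,carbohydrate,19.542,3.879
inc,oil,20.941,2.349
inc,moisture,10.485,0.874
inc,ash,5.187,0.307
inc,protein,47.865,5.142
inc,carbohydrate,15.519,5.602
bkb,oil,4.274,0.440
bkb,moisture,8.927,0.571
bkb,ash,4.293,0.059
bkb,protein,31.398,3.660
bkb,carbohydrate,51.109,3.744
rdb,oil,0.237,0.084
rdb,moisture,14.388,0.526
rdb,ash,2.703,0.164
rdb,protein,18.952,1.768
rdb,carbohydrate,63.687,1.996
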