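sample_id,analyte,mean,sd
cnd,xylose,81.610,1.260
cnd,fructose,95.100,7.120
cnd,sorbitol,163.700,4.290
cnd,galactose,223.000,23.220
cnd,glucose,96.430,34.650
cnd,sucrose,1429.500,88.280
cnd,lactose,132.780,1.500
cnd,maltose,30.630,0.043
pnt,xylose,94.510,6.690
pnt,fructose,462.270,22.870
pnt,sorbitol,158.720,0.517
pnt,galactose,533.750,26.600
pnt,glucose,563.860,47.680
pnt,sucrose,116.660,51.870
pnt,lactose,136.860,2.750
pnt,maltose,34.990,1.530
ssm,xylose,80.970,0.132
ssm,fructose,83.090,2.820
ssm,sorbitol,171.990,1.530
ssm,galactose,210.260,0.515
ssm,glucose,77.080,1.860
ssm,sucrose,1506.260,432.570
ssm,lactose,132.500,1.080
ssm,maltose,33.140,3.720
snf,xylose,81.770,1.230
snf,fructose,80.140,1.520
snf,sorbitol,158.730,0.150
snf,galactose,209.760,0.235
snf,glucose,71.330,1.930
snf,sucrose,2416.240,63.640
snf,lactose,179.480,42.610
snf,maltose,34.500,6.390
inc,xylose,84.270,2.920
inc,fructose,967.780,396.050
inc,sorbitol,158.520,0.336
inc,galactose,226.530,25.490
inc,glucose,961.220,421.290
inc,sucrose,2485.080,192.310
inc,lactose,141.220,16.450
inc,maltose,30.890,0.185
bkb,xylose,80.830,0.286
bkb,fructose,79.100,0.268
bkb,sorbitol,158.570,0.100
bkb,galactose,209.630,0.145
bkb,glucose,64.310,0.461
bkb,sucrose,158.740,54.730
bkb,lactose,131.680,0.015
bkb,maltose,30.780,0.110
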