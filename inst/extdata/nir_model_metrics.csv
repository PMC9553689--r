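method,nutrient,rmsec,sec,r2c,rmsecv,secv,r2cv,rmsep,r2p,sep,rpd
pls,oil,1.611,1.656,0.998,1.540,1.533,0.998,1.733,0.997,1.724,13.208
pls,moisture,0.546,0.562,0.990,0.536,0.532,0.988,0.574,0.989,0.576,6.678
pls,ash,0.335,0.344,0.961,0.333,0.338,0.966,0.359,0.955,0.361,3.245
pls,protein,3.315,3.409,0.950,3.338,3.431,0.936,3.513,0.944,3.525,2.886
pls,carbohydrate,3.780,3.887,0.980,3.734,3.780,0.949,3.979,0.978,3.978,4.666
pcr,oil,1.597,1.643,0.998,1.573,1.501,0.997,1.706,0.997,1.690,13.492
pcr,moisture,0.540,0.556,0.990,0.543,0.519,0.990,0.578,0.989,0.580,6.702
pcr,ash,0.375,0.385,0.951,0.379,0.387,0.942,0.400,0.944,0.401,3.037
pcr,protein,3.858,3.967,0.932,3.895,4.046,0.811,4.078,0.924,4.091,2.608
pcr,carbohydrate,4.280,4.401,0.974,4.373,4.633,0.948,4.550,0.971,4.554,4.175
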