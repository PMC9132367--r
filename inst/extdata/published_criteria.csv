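external,length,alpha,r_sum_full,r_eap_full,r_sum_ext,r_eap_ext,p_sum_adj,p_eap_adj
kq,3,0.25,0.740,0.704,0.390,0.425,0.995,0.995
kq,4,0.42,0.798,0.803,0.431,0.404,0.995,0.995
kq,5,0.52,0.856,0.883,0.456,0.420,0.995,0.995
kq,6,0.56,0.889,0.918,0.507,0.470,0.995,0.83
kq,7,0.56,0.897,0.922,0.511,0.474,0.93,0.53
kq,8,0.59,0.919,0.941,0.526,0.496,0.02,0.0005
kq,9,0.62,0.949,0.971,0.525,0.486,0.01,0.0005
kq,10,0.63,0.962,0.980,0.536,0.495,0.0005,0.0005
kq,11,0.65,0.980,0.995,0.566,0.520,0.0005,0.0005
kq,12,0.64,1,1,0.561,0.521,0.0005,0.0005
who,3,0.25,0.740,0.704,0.396,0.418,0.995,0.995
who,4,0.42,0.798,0.803,0.430,0.395,0.995,0.995
who,5,0.52,0.856,0.883,0.416,0.369,0.995,0.995
who,6,0.56,0.889,0.918,0.457,0.415,0.995,0.995
who,7,0.56,0.897,0.922,0.472,0.426,0.995,0.995
who,8,0.59,0.919,0.941,0.566,0.508,0.0005,0.0005
who,9,0.62,0.949,0.971,0.538,0.476,0.46,0.0005
who,10,0.63,0.962,0.980,0.549,0.483,0.002,0.0005
who,11,0.65,0.980,0.995,0.561,0.496,0.001,0.0005
who,12,0.64,1,1,0.584,0.509,0.001,0.0005
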