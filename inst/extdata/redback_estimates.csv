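parameter,mean,sd,q2.5,q97.5
K,0.473,0.084,0.315,0.641
L,43.461,0.675,42.140,44.761
site2_K,0.162,0.170,-0.162,0.516
site3_K,0.161,0.136,-0.101,0.432
site2_L,1.652,0.883,-0.151,3.270
site3_L,-0.337,0.880,-2.098,1.382
gv_int,2.936,0.490,2.067,3.971
gv_slp,-0.052,0.012,-0.078,-0.030
site2_gv_int,1.490,0.989,-0.318,3.468
site3_gv_int,0.204,0.672,-1.186,1.546
site2_gv_slp,-0.035,0.023,-0.080,0.008
site3_gv_slp,-0.006,0.017,-0.039,0.028
egg_int,-3.157,2.605,-8.333,1.974
egg_slp,0.250,0.057,0.140,0.363
season2_egg_int,-1.292,3.496,-8.063,5.637
season2_egg_slp,0.034,0.078,-0.120,0.186
site2_egg_int,0.434,0.328,-0.201,1.077
site3_egg_int,-0.087,0.294,-0.667,0.472
haz_int,-0.817,0.361,-1.532,-0.145
haz_slp,-0.048,0.009,-0.066,-0.029
season2_haz_int,2.001,0.726,0.498,3.385
season2_haz_slp,-0.050,0.020,-0.089,-0.011
site2_haz_int,0.674,0.158,0.375,0.975
site3_haz_int,0.395,0.130,0.152,0.663
rec_int,-2.120,0.398,-2.929,-1.375
rec_slp,0.031,0.010,0.012,0.051
season2_rec_int,0.472,0.613,-0.715,1.678
season2_rec_slp,-0.014,0.015,-0.044,0.015
site2_rec_int,-0.019,0.137,-0.287,0.245
site3_rec_int,0.097,0.111,-0.122,0.322
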