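province,region,2010,2011,2012,2013,2014,2015,2016,2017,2018,2019
Ningxia,western,1.425,1.547,1.538,1.608,1.651,1.634,1.586,1.562,1.492,1.497
Anhui,central,1.101,1.076,1.075,1.087,1.068,1.063,1.051,1.340,1.318,1.485
Sichuan,western,1.138,1.122,1.144,1.148,1.156,1.126,1.136,1.312,1.439,1.460
Henan,central,1.222,1.227,1.105,1.112,1.124,1.124,1.132,1.122,1.090,1.074
Hubei,central,1.158,1.209,1.299,1.273,1.312,1.316,1.310,1.081,1.091,1.087
Chongqing,western,1.047,1.076,1.086,1.052,1.088,1.082,1.090,1.098,1.081,1.082
Jiangxi,central,1.025,1.080,1.002,1.001,1.028,1.043,1.059,1.054,1.052,1.026
Qinghai,western,1.266,1.253,1.210,1.222,1.155,1.109,1.110,1.072,1.023,1.011
Hunan,central,0.756,1.011,0.797,0.793,1.023,1.041,1.040,1.020,1.062,1.038
Guangxi,western,1.057,1.014,1.037,1.092,1.069,1.049,1.035,0.871,1.001,1.025
Tibet,western,1.127,0.412,1.032,0.430,0.390,0.446,0.468,1.003,1.342,1.252
Yunnan,western,1.065,1.044,1.042,1.025,1.011,1.018,1.019,0.475,0.658,1.004
Guizhou,western,1.101,1.093,1.081,1.056,0.508,0.292,0.319,0.361,0.422,0.446
Xinjiang,western,0.779,0.683,0.624,0.539,0.640,1.001,0.815,0.756,0.733,0.670
Gansu,western,1.006,0.676,0.558,0.650,0.585,0.559,0.565,0.467,0.527,0.442
Heilongjiang,central,1.015,0.634,0.528,0.583,0.573,0.589,0.565,0.393,0.364,0.277
Jilin,central,0.516,0.405,0.420,0.369,0.381,0.323,0.351,0.426,0.466,0.366
Inner Mongolia,western,0.647,0.599,0.509,0.528,0.499,0.508,0.524,0.475,0.475,0.297
Shanxi,central,0.514,0.502,0.468,0.459,0.443,0.410,0.413,0.416,0.451,0.302
Shaanxi,western,0.428,0.303,0.315,0.343,0.307,0.336,0.348,0.255,0.270,0.132
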