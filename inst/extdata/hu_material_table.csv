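range,hu_lo,hu_hi,rho_lo,rho_hi,H,C,N,O,Na,Mg,P,S,Cl,Ar,K,Ca
1,-1050,-950,0.001,0.044,0.000,0.000,0.755,0.232,0.000,0.000,0.000,0.000,0.000,0.013,0.000,0.000
2,-950,-120,0.044,0.926,0.103,0.105,0.031,0.749,0.002,0.000,0.002,0.003,0.003,0.000,0.002,0.000
3,-120,-83,0.926,0.957,0.116,0.681,0.002,0.198,0.001,0.000,0.000,0.001,0.001,0.000,0.000,0.000
4,-83,-53,0.930,0.960,0.110,0.527,0.013,0.345,0.001,0.000,0.001,0.002,0.001,0.000,0.000,0.000
5,-53,-23,0.960,0.980,0.108,0.413,0.025,0.448,0.001,0.000,0.001,0.002,0.002,0.000,0.000,0.000
6,-23,7,0.980,1.000,0.106,0.284,0.026,0.578,0.001,0.000,0.001,0.002,0.002,0.000,0.000,0.000
7,7,18,1.000,1.010,0.103,0.134,0.030,0.723,0.002,0.000,0.002,0.002,0.002,0.000,0.002,0.000
8,18,80,1.010,1.040,0.102,0.143,0.034,0.710,0.001,0.000,0.002,0.003,0.001,0.000,0.004,0.000
9,80,120,1.040,1.070,0.094,0.207,0.062,0.622,0.006,0.000,0.000,0.006,0.003,0.000,0.000,0.000
10,120,200,1.070,1.120,0.095,0.454,0.025,0.355,0.001,0.001,0.021,0.001,0.001,0.000,0.001,0.045
11,200,400,1.120,1.250,0.089,0.422,0.027,0.363,0.001,0.001,0.030,0.001,0.001,0.000,0.001,0.064
12,400,800,1.250,1.480,0.078,0.316,0.037,0.438,0.001,0.001,0.040,0.002,0.001,0.000,0.001,0.085
13,800,1200,1.480,1.710,0.066,0.251,0.039,0.435,0.001,0.001,0.061,0.002,0.001,0.000,0.001,0.142
14,1200,3000,1.710,2.700,0.056,0.235,0.042,0.430,0.001,0.002,0.072,0.003,0.000,0.000,0.000,0.159
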