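energy_MeV,mu0_per_mm
0.5,0.00969
1.0,0.00707
1.5,0.00575
2.0,0.00494
2.5,0.00443
3.0,0.00397
3.5,0.00363
4.0,0.00340
5.0,0.00303
6.0,0.00277
7.0,0.00255
8.0,0.00240
9.0,0.00231
10.0,0.00222
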