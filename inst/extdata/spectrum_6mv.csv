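energy_MeV,weight
0.5,0.220
1.0,0.230
1.5,0.170
2.0,0.120
2.5,0.085
3.0,0.060
3.5,0.042
4.0,0.030
5.0,0.028
6.0,0.015
7.0,0.000
8.0,0.000
9.0,0.000
10.0,0.000
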