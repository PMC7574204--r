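time_h,dcw_g_l,lipid_g_l,glucose_g_l,xylose_g_l,arabinose_g_l
0,0.1,0,28.05,18.13,0.29
12,0.326,0.1,23.97,18.13,0.29
24,1.02,0.407,19.89,18.13,0.29
36,2.85,1.219,15.81,18.13,0.29
48,6.201,2.731,11.73,18.13,0.29
60,9.6,4.343,7.65,18.13,0.29
72,11.498,5.392,3.57,18.13,0.29
84,12.227,5.982,0,17.23,0.29
96,12.464,6.378,0,10.03,0.29
108,12.538,6.709,0,2.83,0.29
120,12.56,7.02,0,0,0
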