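condition,time_h,dcw_g_l,lipid_g_l
AS-PSH,120,12.56,7.02
AD-PSH,120,10.63,4.48
YNB,120,12.26,6.65
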