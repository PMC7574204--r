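ps_loading_pct,dcw_g_l,lipid_g_l,biodiesel_g_l
20,12.8,6.8,6.24
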