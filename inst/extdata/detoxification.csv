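quantity,before,after
acid_liquid_total_sugars_g_l,37.38,31.91
acetic_acid_g_l,5.61,0.11
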