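analyte,unit,before,after
glucose,g/L,0.45,
xylose,g/L,29.01,
arabinose,g/L,2.45,
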