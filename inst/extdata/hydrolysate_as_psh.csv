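analyte,unit,before,after
glucose,g/L,28.05,
xylose,g/L,18.13,0.05
arabinose,g/L,0.29,
total proteins,g/L,0.33,0.23
total nitrogen,g/L,0.053,0.037
calcium,mg/L,107,6.3
sodium,g/L,1.08,0.84
magnesium,g/L,1.53,0.22
phosphorous,g/L,1.51,0.36
potassium,g/L,1.53,0.38
manganese,mg/L,0.37,0.24
iron,mg/L,0.067,0.036
5-HMF,g/L,0.013,0.01
acetic acid,g/L,0.046,
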