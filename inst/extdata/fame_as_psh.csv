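species,wt_percent
C14:0,0.89
C15:0,0.1
C16:0,28.85
C18:1,52.58
C18:2,12.45
C18:3,1.37
C22:0,0.46
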