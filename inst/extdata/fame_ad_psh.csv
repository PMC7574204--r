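species,wt_percent
C16:0,14.45
C18:0,6.13
C18:1,61.98
C18:2,16.86
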