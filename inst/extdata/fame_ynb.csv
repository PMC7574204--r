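species,wt_percent
C14:0,0.55
C16:0,10.4
C18:1,43.61
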