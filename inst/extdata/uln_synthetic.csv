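SEX,AGE_LO,AGE_HI,ULN
male,0,15,35
male,15,120,70
female,0,15,30
female,15,120,40
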