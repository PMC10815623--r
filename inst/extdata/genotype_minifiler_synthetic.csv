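M1,10/12
M2,8
M3,9/11
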