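method,Dye-B,Dye-G,Dye-Y,Dye-R,Dye-P
AT_ori,175,175,175,175,175
AT1,16,24,18,22,25
AT2,11,16,11,15,17
AT3,17,24,18,23,25
AT4,16,22,16,21,23
AT5,22,32,23,29,32
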