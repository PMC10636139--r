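small,intermediate,large
6,1,0
0,18,4
0,1,8
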