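small,intermediate,large
6,1,0
0,14,8
0,0,9
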