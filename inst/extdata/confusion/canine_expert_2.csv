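small,intermediate,large
5,0,0
2,6,1
0,1,10
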