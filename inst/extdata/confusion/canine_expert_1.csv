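small,intermediate,large
4,0,0
2,5,2
0,4,7
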