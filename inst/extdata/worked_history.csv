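1,2,3,4,4
2,3,2,4,5
1,3,3,5,5
1,2,3,4,4
1,3,3,3,5
2,1,3,4,5
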