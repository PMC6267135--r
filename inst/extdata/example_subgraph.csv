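1,3
3,15
15,6
6,27
3,27
27,4
27,20
27,30
20,4
20,30
30,4
30,13
13,4
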