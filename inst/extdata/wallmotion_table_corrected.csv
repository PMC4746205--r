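score,0,1,2,3,4
0,705,18,3,2,0
1,2,1,1,3,3
2,1,1,1,5,2
3,0,0,0,0,0
4,0,0,0,0,0
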