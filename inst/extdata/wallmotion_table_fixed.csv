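score,0,1,2,3,4
0,694,13,1,0,0
1,12,5,1,2,2
2,2,2,3,7,3
3,0,0,0,1,0
4,0,0,0,0,0
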