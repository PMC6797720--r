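day,mean_count,sd
1,1,0
3,13,0
5,61,0
7,265,0
9,685,0
11,1301,0
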