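sentence_id,mean_score,sd_score
7,2.5,0.55
10,3.2,0.75
3,3.8,0.41
6,3.8,0.41
11,4.5,0.55
5,5.0,0.00
2,6.0,0.00
9,6.0,0.00
4,6.2,0.41
8,7.0,0.63
1,7.2,0.75
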