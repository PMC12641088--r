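sentence_id,adverb,tense,category
1,next_week,present,future
2,this_week,present,future
3,yesterday,past,past
4,tomorrow,present,future
5,now,past,present
6,yesterday,past,past
7,last_week,past,past
8,next_week,present,future
9,this_week,present,future
10,last_week,past,past
11,today,past,past
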