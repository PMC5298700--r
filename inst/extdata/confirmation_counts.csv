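participant,defined,correct,incorrect
1,3,45,0
2,3,28,3
3,4,42,0
4,5,33,5
5,3,38,4
6,6,54,0
7,5,60,9
8,5,73,11
9,4,14,4
10,4,10,1
11,3,43,1
12,6,11,1
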