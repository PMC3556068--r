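fold,MLR,XCSF,ANN
1,0.6163,0.16,0.3202
2,0.246,0.196,0.2509
3,0.2678,0.207,0.2678
4,0.3259,0.192,0.2428
5,0.3857,0.186,0.2464
6,0.1724,0.187,0.1918
7,0.25,0.221,0.2979
8,0.2135,0.192,0.2216
9,0.304,0.18,0.2085
10,0.326,0.185,0.3063
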