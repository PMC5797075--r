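sample_id,hb_g_per_l
1,114
2,144
3,123
4,114
5,111
6,146
7,135
8,102
9,127
10,132
11,116
12,116
13,101
14,151
15,143
16,118
17,106
18,125
19,161
20,114
21,110
22,131
23,154
24,130
25,128
26,137
27,146
28,133
29,136
30,120
31,141
32,126
33,118
34,128
35,98
36,133
37,72
38,88
39,82
40,105
41,128
42,134
43,107
44,108
45,123
46,142
47,154
48,128
49,134
50,124
51,129
52,135
53,137
54,126
55,110
56,122
57,150
58,115
59,94
60,83
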