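# Synthetic period life table calibrated to 2009 US total-population mortality.
# Gompertz-Makeham hazard lambda + exp(beta*(age - modal)) with
# lambda=0.0043424, beta=0.115, modal=106.52, fitted to published 2009 qx
# anchors at ages 65-95. Not a transcription of the official table.
age,qx
50,0.005829084
51,0.006011265
52,0.00621561
53,0.006444808
54,0.006701877
55,0.006990196
56,0.007313554
57,0.007676196
58,0.008082877
59,0.008538922
60,0.009050298
61,0.009623683
62,0.01026655
63,0.01098728
64,0.01179521
65,0.01270083
66,0.01371582
67,0.01485328
68,0.0161278
69,0.01755569
70,0.01915514
71,0.02094642
72,0.02295211
73,0.02519735
74,0.02771009
75,0.03052135
76,0.03366556
77,0.03718083
78,0.0411093
79,0.04549747
80,0.05039654
81,0.05586276
82,0.06195773
83,0.06874869
84,0.07630878
85,0.08471723
86,0.09405937
87,0.1044266
88,0.1159162
89,0.1286308
90,0.1426773
91,0.1581665
92,0.1752105
93,0.1939214
94,0.2144079
95,0.236772
96,0.2611049
97,0.2874812
98,0.3159529
99,0.3465428
100,0.3792355
101,0.4139698
102,0.4506293
103,0.4890342
104,0.5289333
105,0.5699988
106,0.6118236
107,0.6539231
108,0.6957435
109,0.7366761
110,1
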