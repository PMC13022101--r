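index,hex
0,#440154
1,#440256
2,#450457
3,#450559
4,#46075A
5,#46085C
6,#460A5D
7,#460B5E
8,#470D60
9,#470E61
10,#471063
11,#471164
12,#471365
13,#481467
14,#481668
15,#481769
16,#48186A
17,#481A6C
18,#481B6D
19,#481C6E
20,#481D6F
21,#481F70
22,#482071
23,#482173
24,#482374
25,#482475
26,#482576
27,#482677
28,#482878
29,#482979
30,#472A7A
31,#472C7A
32,#472D7B
33,#472E7C
34,#472F7D
35,#46307E
36,#46327E
37,#46337F
38,#463480
39,#453581
40,#453781
41,#453882
42,#443983
43,#443A83
44,#443B84
45,#433D84
46,#433E85
47,#423F85
48,#424086
49,#424186
50,#414287
51,#414487
52,#404588
53,#404688
54,#3F4788
55,#3F4889
56,#3E4989
57,#3E4A89
58,#3E4C8A
59,#3D4D8A
60,#3D4E8A
61,#3C4F8A
62,#3C508B
63,#3B518B
64,#3B528B
65,#3A538B
66,#3A548C
67,#39558C
68,#39568C
69,#38588C
70,#38598C
71,#375A8C
72,#375B8D
73,#365C8D
74,#365D8D
75,#355E8D
76,#355F8D
77,#34608D
78,#34618D
79,#33628D
80,#33638D
81,#32648E
82,#32658E
83,#31668E
84,#31678E
85,#31688E
86,#30698E
87,#306A8E
88,#2F6B8E
89,#2F6C8E
90,#2E6D8E
91,#2E6E8E
92,#2E6F8E
93,#2D708E
94,#2D718E
95,#2C718E
96,#2C728E
97,#2C738E
98,#2B748E
99,#2B758E
100,#2A768E
101,#2A778E
102,#2A788E
103,#29798E
104,#297A8E
105,#297B8E
106,#287C8E
107,#287D8E
108,#277E8E
109,#277F8E
110,#27808E
111,#26818E
112,#26828E
113,#26828E
114,#25838E
115,#25848E
116,#25858E
117,#24868E
118,#24878E
119,#23888E
120,#23898E
121,#238A8D
122,#228B8D
123,#228C8D
124,#228D8D
125,#218E8D
126,#218F8D
127,#21908D
128,#21918C
129,#20928C
130,#20928C
131,#20938C
132,#1F948C
133,#1F958B
134,#1F968B
135,#1F978B
136,#1F988B
137,#1F998A
138,#1F9A8A
139,#1E9B8A
140,#1E9C89
141,#1E9D89
142,#1F9E89
143,#1F9F88
144,#1FA088
145,#1FA188
146,#1FA187
147,#1FA287
148,#20A386
149,#20A486
150,#21A585
151,#21A685
152,#22A785
153,#22A884
154,#23A983
155,#24AA83
156,#25AB82
157,#25AC82
158,#26AD81
159,#27AD81
160,#28AE80
161,#29AF7F
162,#2AB07F
163,#2CB17E
164,#2DB27D
165,#2EB37C
166,#2FB47C
167,#31B57B
168,#32B67A
169,#34B679
170,#35B779
171,#37B878
172,#38B977
173,#3ABA76
174,#3BBB75
175,#3DBC74
176,#3FBC73
177,#40BD72
178,#42BE71
179,#44BF70
180,#46C06F
181,#48C16E
182,#4AC16D
183,#4CC26C
184,#4EC36B
185,#50C46A
186,#52C569
187,#54C568
188,#56C667
189,#58C765
190,#5AC864
191,#5CC863
192,#5EC962
193,#60CA60
194,#63CB5F
195,#65CB5E
196,#67CC5C
197,#69CD5B
198,#6CCD5A
199,#6ECE58
200,#70CF57
201,#73D056
202,#75D054
203,#77D153
204,#7AD151
205,#7CD250
206,#7FD34E
207,#81D34D
208,#84D44B
209,#86D549
210,#89D548
211,#8BD646
212,#8ED645
213,#90D743
214,#93D741
215,#95D840
216,#98D83E
217,#9BD93C
218,#9DD93B
219,#A0DA39
220,#A2DA37
221,#A5DB36
222,#A8DB34
223,#AADC32
224,#ADDC30
225,#B0DD2F
226,#B2DD2D
227,#B5DE2B
228,#B8DE29
229,#BADE28
230,#BDDF26
231,#C0DF25
232,#C2DF23
233,#C5E021
234,#C8E020
235,#CAE11F
236,#CDE11D
237,#D0E11C
238,#D2E21B
239,#D5E21A
240,#D8E219
241,#DAE319
242,#DDE318
243,#DFE318
244,#E2E418
245,#E5E419
246,#E7E419
247,#EAE51A
248,#ECE51B
249,#EFE51C
250,#F1E51D
251,#F4E61E
252,#F6E620
253,#F8E621
254,#FBE723
255,#FDE725
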