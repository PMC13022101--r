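index,hex
0,#000004
1,#010005
2,#010106
3,#010108
4,#020109
5,#02020B
6,#02020D
7,#03030F
8,#030312
9,#040414
10,#050416
11,#060518
12,#06051A
13,#07061C
14,#08071E
15,#090720
16,#0A0822
17,#0B0924
18,#0C0926
19,#0D0A29
20,#0E0B2B
21,#100B2D
22,#110C2F
23,#120D31
24,#130D34
25,#140E36
26,#150E38
27,#160F3B
28,#180F3D
29,#19103F
30,#1A1042
31,#1C1044
32,#1D1147
33,#1E1149
34,#20114B
35,#21114E
36,#221150
37,#241253
38,#251255
39,#271258
40,#29115A
41,#2A115C
42,#2C115F
43,#2D1161
44,#2F1163
45,#311165
46,#331067
47,#341069
48,#36106B
49,#38106C
50,#390F6E
51,#3B0F70
52,#3D0F71
53,#3F0F72
54,#400F74
55,#420F75
56,#440F76
57,#451077
58,#471078
59,#491078
60,#4A1079
61,#4C117A
62,#4E117B
63,#4F127B
64,#51127C
65,#52137C
66,#54137D
67,#56147D
68,#57157E
69,#59157E
70,#5A167E
71,#5C167F
72,#5D177F
73,#5F187F
74,#601880
75,#621980
76,#641A80
77,#651A80
78,#671B80
79,#681C81
80,#6A1C81
81,#6B1D81
82,#6D1D81
83,#6E1E81
84,#701F81
85,#721F81
86,#732081
87,#752181
88,#762181
89,#782281
90,#792282
91,#7B2382
92,#7C2382
93,#7E2482
94,#802582
95,#812581
96,#832681
97,#842681
98,#862781
99,#882781
100,#892881
101,#8B2981
102,#8C2981
103,#8E2A81
104,#902A81
105,#912B81
106,#932B80
107,#942C80
108,#962C80
109,#982D80
110,#992D80
111,#9B2E7F
112,#9C2E7F
113,#9E2F7F
114,#A02F7F
115,#A1307E
116,#A3307E
117,#A5317E
118,#A6317D
119,#A8327D
120,#AA337D
121,#AB337C
122,#AD347C
123,#AE347B
124,#B0357B
125,#B2357B
126,#B3367A
127,#B5367A
128,#B73779
129,#B83779
130,#BA3878
131,#BC3978
132,#BD3977
133,#BF3A77
134,#C03A76
135,#C23B75
136,#C43C75
137,#C53C74
138,#C73D73
139,#C83E73
140,#CA3E72
141,#CC3F71
142,#CD4071
143,#CF4070
144,#D0416F
145,#D2426F
146,#D3436E
147,#D5446D
148,#D6456C
149,#D8456C
150,#D9466B
151,#DB476A
152,#DC4869
153,#DE4968
154,#DF4A68
155,#E04C67
156,#E24D66
157,#E34E65
158,#E44F64
159,#E55064
160,#E75263
161,#E85362
162,#E95462
163,#EA5661
164,#EB5760
165,#EC5860
166,#ED5A5F
167,#EE5B5E
168,#EF5D5E
169,#F05F5E
170,#F1605D
171,#F2625D
172,#F2645C
173,#F3655C
174,#F4675C
175,#F4695C
176,#F56B5C
177,#F66C5C
178,#F66E5C
179,#F7705C
180,#F7725C
181,#F8745C
182,#F8765C
183,#F9785D
184,#F9795D
185,#F97B5D
186,#FA7D5E
187,#FA7F5E
188,#FA815F
189,#FB835F
190,#FB8560
191,#FB8761
192,#FC8961
193,#FC8A62
194,#FC8C63
195,#FC8E64
196,#FC9065
197,#FD9266
198,#FD9467
199,#FD9668
200,#FD9869
201,#FD9A6A
202,#FD9B6B
203,#FE9D6C
204,#FE9F6D
205,#FEA16E
206,#FEA36F
207,#FEA571
208,#FEA772
209,#FEA973
210,#FEAA74
211,#FEAC76
212,#FEAE77
213,#FEB078
214,#FEB27A
215,#FEB47B
216,#FEB67C
217,#FEB77E
218,#FEB97F
219,#FEBB81
220,#FEBD82
221,#FEBF84
222,#FEC185
223,#FEC287
224,#FEC488
225,#FEC68A
226,#FEC88C
227,#FECA8D
228,#FECC8F
229,#FECD90
230,#FECF92
231,#FED194
232,#FED395
233,#FED597
234,#FED799
235,#FED89A
236,#FDDA9C
237,#FDDC9E
238,#FDDEA0
239,#FDE0A1
240,#FDE2A3
241,#FDE3A5
242,#FDE5A7
243,#FDE7A9
244,#FDE9AA
245,#FDEBAC
246,#FCECAE
247,#FCEEB0
248,#FCF0B2
249,#FCF2B4
250,#FCF4B6
251,#FCF6B8
252,#FCF7B9
253,#FCF9BB
254,#FCFBBD
255,#FCFDBF
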