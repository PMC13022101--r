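index,hex
0,#30123B
1,#321543
2,#33184A
3,#341B51
4,#351E58
5,#36215F
6,#372466
7,#38276D
8,#392A73
9,#3A2D79
10,#3B2F80
11,#3C3286
12,#3D358B
13,#3E3891
14,#3F3B97
15,#3F3E9C
16,#4040A2
17,#4143A7
18,#4146AC
19,#4249B1
20,#424BB5
21,#434EBA
22,#4451BF
23,#4454C3
24,#4456C7
25,#4559CB
26,#455CCF
27,#455ED3
28,#4661D6
29,#4664DA
30,#4666DD
31,#4669E0
32,#466BE3
33,#476EE6
34,#4771E9
35,#4773EB
36,#4776EE
37,#4778F0
38,#477BF2
39,#467DF4
40,#4680F6
41,#4682F8
42,#4685FA
43,#4687FB
44,#458AFC
45,#458CFD
46,#448FFE
47,#4391FE
48,#4294FF
49,#4196FF
50,#4099FF
51,#3E9BFE
52,#3D9EFE
53,#3BA0FD
54,#3AA3FC
55,#38A5FB
56,#37A8FA
57,#35ABF8
58,#33ADF7
59,#31AFF5
60,#2FB2F4
61,#2EB4F2
62,#2CB7F0
63,#2AB9EE
64,#28BCEB
65,#27BEE9
66,#25C0E7
67,#23C3E4
68,#22C5E2
69,#20C7DF
70,#1FC9DD
71,#1ECBDA
72,#1CCDD8
73,#1BD0D5
74,#1AD2D2
75,#1AD4D0
76,#19D5CD
77,#18D7CA
78,#18D9C8
79,#18DBC5
80,#18DDC2
81,#18DEC0
82,#18E0BD
83,#19E2BB
84,#19E3B9
85,#1AE4B6
86,#1CE6B4
87,#1DE7B2
88,#1FE9AF
89,#20EAAC
90,#22EBAA
91,#25ECA7
92,#27EEA4
93,#2AEFA1
94,#2CF09E
95,#2FF19B
96,#32F298
97,#35F394
98,#38F491
99,#3CF58E
100,#3FF68A
101,#43F787
102,#46F884
103,#4AF880
104,#4EF97D
105,#52FA7A
106,#55FA76
107,#59FB73
108,#5DFC6F
109,#61FC6C
110,#65FD69
111,#69FD66
112,#6DFE62
113,#71FE5F
114,#75FE5C
115,#79FE59
116,#7DFF56
117,#80FF53
118,#84FF51
119,#88FF4E
120,#8BFF4B
121,#8FFF49
122,#92FF47
123,#96FE44
124,#99FE42
125,#9CFE40
126,#9FFD3F
127,#A1FD3D
128,#A4FC3C
129,#A7FC3A
130,#A9FB39
131,#ACFB38
132,#AFFA37
133,#B1F936
134,#B4F836
135,#B7F735
136,#B9F635
137,#BCF534
138,#BEF434
139,#C1F334
140,#C3F134
141,#C6F034
142,#C8EF34
143,#CBED34
144,#CDEC34
145,#D0EA34
146,#D2E935
147,#D4E735
148,#D7E535
149,#D9E436
150,#DBE236
151,#DDE037
152,#DFDF37
153,#E1DD37
154,#E3DB38
155,#E5D938
156,#E7D739
157,#E9D539
158,#EBD339
159,#ECD13A
160,#EECF3A
161,#EFCD3A
162,#F1CB3A
163,#F2C93A
164,#F4C73A
165,#F5C53A
166,#F6C33A
167,#F7C13A
168,#F8BE39
169,#F9BC39
170,#FABA39
171,#FBB838
172,#FBB637
173,#FCB336
174,#FCB136
175,#FDAE35
176,#FDAC34
177,#FEA933
178,#FEA732
179,#FEA431
180,#FEA130
181,#FE9E2F
182,#FE9B2D
183,#FE992C
184,#FE962B
185,#FE932A
186,#FE9029
187,#FD8D27
188,#FD8A26
189,#FC8725
190,#FC8423
191,#FB8122
192,#FB7E21
193,#FA7B1F
194,#F9781E
195,#F9751D
196,#F8721C
197,#F76F1A
198,#F66C19
199,#F56918
200,#F46617
201,#F36315
202,#F26014
203,#F15D13
204,#F05B12
205,#EF5811
206,#ED5510
207,#EC530F
208,#EB500E
209,#EA4E0D
210,#E84B0C
211,#E7490C
212,#E5470B
213,#E4450A
214,#E2430A
215,#E14109
216,#DF3F08
217,#DD3D08
218,#DC3B07
219,#DA3907
220,#D83706
221,#D63506
222,#D43305
223,#D23105
224,#D02F05
225,#CE2D04
226,#CC2B04
227,#CA2A04
228,#C82803
229,#C52603
230,#C32503
231,#C12302
232,#BE2102
233,#BC2002
234,#B91E02
235,#B71D02
236,#B41B01
237,#B21A01
238,#AF1801
239,#AC1701
240,#A91601
241,#A71401
242,#A41301
243,#A11201
244,#9E1001
245,#9B0F01
246,#980E01
247,#950D01
248,#920B01
249,#8E0A01
250,#8B0902
251,#880802
252,#850702
253,#810602
254,#7E0502
255,#7A0403
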