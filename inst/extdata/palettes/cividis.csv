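index,hex
0,#00224E
1,#00234F
2,#002451
3,#002553
4,#002554
5,#002656
6,#002758
7,#002859
8,#00285B
9,#00295D
10,#002A5F
11,#002A61
12,#002B62
13,#002C64
14,#002C66
15,#002D68
16,#002E6A
17,#002E6C
18,#002F6D
19,#00306F
20,#003070
21,#003170
22,#003171
23,#013271
24,#053371
25,#083370
26,#0C3470
27,#0F3570
28,#123570
29,#143670
30,#163770
31,#18376F
32,#1A386F
33,#1C396F
34,#1E3A6F
35,#203A6F
36,#213B6E
37,#233C6E
38,#243C6E
39,#263D6E
40,#273E6E
41,#293F6E
42,#2A3F6D
43,#2B406D
44,#2D416D
45,#2E416D
46,#2F426D
47,#31436D
48,#32436D
49,#33446D
50,#34456C
51,#35456C
52,#36466C
53,#38476C
54,#39486C
55,#3A486C
56,#3B496C
57,#3C4A6C
58,#3D4A6C
59,#3E4B6C
60,#3F4C6C
61,#404C6C
62,#414D6C
63,#424E6C
64,#434E6C
65,#444F6C
66,#45506C
67,#46516C
68,#47516C
69,#48526C
70,#49536C
71,#4A536C
72,#4B546C
73,#4C556C
74,#4D556C
75,#4E566C
76,#4F576C
77,#50576C
78,#51586D
79,#52596D
80,#535A6D
81,#545A6D
82,#555B6D
83,#555C6D
84,#565C6D
85,#575D6D
86,#585E6D
87,#595E6E
88,#5A5F6E
89,#5B606E
90,#5C616E
91,#5D616E
92,#5E626E
93,#5E636F
94,#5F636F
95,#60646F
96,#61656F
97,#62656F
98,#636670
99,#646770
100,#656870
101,#656870
102,#666970
103,#676A71
104,#686A71
105,#696B71
106,#6A6C71
107,#6B6D72
108,#6C6D72
109,#6C6E72
110,#6D6F72
111,#6E6F73
112,#6F7073
113,#707173
114,#717274
115,#727274
116,#727374
117,#737475
118,#747475
119,#757575
120,#767676
121,#777776
122,#777777
123,#787877
124,#797977
125,#7A7A78
126,#7B7A78
127,#7C7B78
128,#7D7C78
129,#7E7C78
130,#7E7D78
131,#7F7E78
132,#807F78
133,#817F78
134,#828079
135,#838179
136,#848279
137,#858279
138,#868379
139,#878478
140,#888578
141,#898578
142,#8A8678
143,#8B8778
144,#8C8878
145,#8D8878
146,#8E8978
147,#8F8A78
148,#908B78
149,#918B78
150,#928C78
151,#928D78
152,#938E78
153,#948E77
154,#958F77
155,#969077
156,#979177
157,#989277
158,#999277
159,#9A9376
160,#9B9476
161,#9C9576
162,#9D9576
163,#9E9676
164,#9F9775
165,#A09875
166,#A19975
167,#A29975
168,#A39A74
169,#A49B74
170,#A59C74
171,#A69C74
172,#A79D73
173,#A89E73
174,#A99F73
175,#AAA073
176,#ABA072
177,#ACA172
178,#ADA272
179,#AEA371
180,#AFA471
181,#B0A571
182,#B1A570
183,#B3A670
184,#B4A76F
185,#B5A86F
186,#B6A96F
187,#B7A96E
188,#B8AA6E
189,#B9AB6D
190,#BAAC6D
191,#BBAD6D
192,#BCAE6C
193,#BDAE6C
194,#BEAF6B
195,#BFB06B
196,#C0B16A
197,#C1B26A
198,#C2B369
199,#C3B369
200,#C4B468
201,#C5B568
202,#C6B667
203,#C7B767
204,#C8B866
205,#C9B965
206,#CBB965
207,#CCBA64
208,#CDBB63
209,#CEBC63
210,#CFBD62
211,#D0BE62
212,#D1BF61
213,#D2C060
214,#D3C05F
215,#D4C15F
216,#D5C25E
217,#D6C35D
218,#D7C45C
219,#D9C55C
220,#DAC65B
221,#DBC75A
222,#DCC859
223,#DDC858
224,#DEC958
225,#DFCA57
226,#E0CB56
227,#E1CC55
228,#E2CD54
229,#E4CE53
230,#E5CF52
231,#E6D051
232,#E7D150
233,#E8D24F
234,#E9D34E
235,#EAD34C
236,#EBD44B
237,#EDD54A
238,#EED649
239,#EFD748
240,#F0D846
241,#F1D945
242,#F2DA44
243,#F3DB42
244,#F5DC41
245,#F6DD3F
246,#F7DE3E
247,#F8DF3C
248,#F9E03A
249,#FBE138
250,#FCE236
251,#FDE334
252,#FEE434
253,#FEE535
254,#FEE636
255,#FEE838
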