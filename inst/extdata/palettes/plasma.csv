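index,hex
0,#0D0887
1,#100788
2,#130789
3,#16078A
4,#19068C
5,#1B068D
6,#1D068E
7,#20068F
8,#220690
9,#240691
10,#260591
11,#280592
12,#2A0593
13,#2C0594
14,#2E0595
15,#2F0596
16,#310597
17,#330597
18,#350498
19,#370499
20,#38049A
21,#3A049A
22,#3C049B
23,#3E049C
24,#3F049C
25,#41049D
26,#43039E
27,#44039E
28,#46039F
29,#48039F
30,#4903A0
31,#4B03A1
32,#4C02A1
33,#4E02A2
34,#5002A2
35,#5102A3
36,#5302A3
37,#5502A4
38,#5601A4
39,#5801A4
40,#5901A5
41,#5B01A5
42,#5C01A6
43,#5E01A6
44,#6001A6
45,#6100A7
46,#6300A7
47,#6400A7
48,#6600A7
49,#6700A8
50,#6900A8
51,#6A00A8
52,#6C00A8
53,#6E00A8
54,#6F00A8
55,#7100A8
56,#7201A8
57,#7401A8
58,#7501A8
59,#7701A8
60,#7801A8
61,#7A02A8
62,#7B02A8
63,#7D03A8
64,#7E03A8
65,#8004A8
66,#8104A7
67,#8305A7
68,#8405A7
69,#8606A6
70,#8707A6
71,#8808A6
72,#8A09A5
73,#8B0AA5
74,#8D0BA5
75,#8E0CA4
76,#8F0DA4
77,#910EA3
78,#920FA3
79,#9410A2
80,#9511A1
81,#9613A1
82,#9814A0
83,#99159F
84,#9A169F
85,#9C179E
86,#9D189D
87,#9E199D
88,#A01A9C
89,#A11B9B
90,#A21D9A
91,#A31E9A
92,#A51F99
93,#A62098
94,#A72197
95,#A82296
96,#AA2395
97,#AB2494
98,#AC2694
99,#AD2793
100,#AE2892
101,#B02991
102,#B12A90
103,#B22B8F
104,#B32C8E
105,#B42E8D
106,#B52F8C
107,#B6308B
108,#B7318A
109,#B83289
110,#BA3388
111,#BB3488
112,#BC3587
113,#BD3786
114,#BE3885
115,#BF3984
116,#C03A83
117,#C13B82
118,#C23C81
119,#C33D80
120,#C43E7F
121,#C5407E
122,#C6417D
123,#C7427C
124,#C8437B
125,#C9447A
126,#CA457A
127,#CB4679
128,#CC4778
129,#CC4977
130,#CD4A76
131,#CE4B75
132,#CF4C74
133,#D04D73
134,#D14E72
135,#D24F71
136,#D35171
137,#D45270
138,#D5536F
139,#D5546E
140,#D6556D
141,#D7566C
142,#D8576B
143,#D9586A
144,#DA5A6A
145,#DA5B69
146,#DB5C68
147,#DC5D67
148,#DD5E66
149,#DE5F65
150,#DE6164
151,#DF6263
152,#E06363
153,#E16462
154,#E26561
155,#E26660
156,#E3685F
157,#E4695E
158,#E56A5D
159,#E56B5D
160,#E66C5C
161,#E76E5B
162,#E76F5A
163,#E87059
164,#E97158
165,#E97257
166,#EA7457
167,#EB7556
168,#EB7655
169,#EC7754
170,#ED7953
171,#ED7A52
172,#EE7B51
173,#EF7C51
174,#EF7E50
175,#F07F4F
176,#F0804E
177,#F1814D
178,#F1834C
179,#F2844B
180,#F3854B
181,#F3874A
182,#F48849
183,#F48948
184,#F58B47
185,#F58C46
186,#F68D45
187,#F68F44
188,#F79044
189,#F79143
190,#F79342
191,#F89441
192,#F89540
193,#F9973F
194,#F9983E
195,#F99A3E
196,#FA9B3D
197,#FA9C3C
198,#FA9E3B
199,#FB9F3A
200,#FBA139
201,#FBA238
202,#FCA338
203,#FCA537
204,#FCA636
205,#FCA835
206,#FCA934
207,#FDAB33
208,#FDAC33
209,#FDAE32
210,#FDAF31
211,#FDB130
212,#FDB22F
213,#FDB42F
214,#FDB52E
215,#FEB72D
216,#FEB82C
217,#FEBA2C
218,#FEBB2B
219,#FEBD2A
220,#FEBE2A
221,#FEC029
222,#FDC229
223,#FDC328
224,#FDC527
225,#FDC627
226,#FDC827
227,#FDCA26
228,#FDCB26
229,#FCCD25
230,#FCCE25
231,#FCD025
232,#FCD225
233,#FBD324
234,#FBD524
235,#FBD724
236,#FAD824
237,#FADA24
238,#F9DC24
239,#F9DD25
240,#F8DF25
241,#F8E125
242,#F7E225
243,#F7E425
244,#F6E626
245,#F6E826
246,#F5E926
247,#F5EB27
248,#F4ED27
249,#F3EE27
250,#F3F027
251,#F2F227
252,#F1F426
253,#F1F525
254,#F0F724
255,#F0F921
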