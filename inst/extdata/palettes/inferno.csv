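index,hex
0,#000004
1,#010005
2,#010106
3,#010108
4,#02010A
5,#02020C
6,#02020E
7,#030210
8,#040312
9,#040314
10,#050417
11,#060419
12,#07051B
13,#08051D
14,#09061F
15,#0A0722
16,#0B0724
17,#0C0826
18,#0D0829
19,#0E092B
20,#10092D
21,#110A30
22,#120A32
23,#140B34
24,#150B37
25,#160B39
26,#180C3C
27,#190C3E
28,#1B0C41
29,#1C0C43
30,#1E0C45
31,#1F0C48
32,#210C4A
33,#230C4C
34,#240C4F
35,#260C51
36,#280B53
37,#290B55
38,#2B0B57
39,#2D0B59
40,#2F0A5B
41,#310A5C
42,#320A5E
43,#340A5F
44,#360961
45,#380962
46,#390963
47,#3B0964
48,#3D0965
49,#3E0966
50,#400A67
51,#420A68
52,#440A68
53,#450A69
54,#470B6A
55,#490B6A
56,#4A0C6B
57,#4C0C6B
58,#4D0D6C
59,#4F0D6C
60,#510E6C
61,#520E6D
62,#540F6D
63,#550F6D
64,#57106E
65,#59106E
66,#5A116E
67,#5C126E
68,#5D126E
69,#5F136E
70,#61136E
71,#62146E
72,#64156E
73,#65156E
74,#67166E
75,#69166E
76,#6A176E
77,#6C186E
78,#6D186E
79,#6F196E
80,#71196E
81,#721A6E
82,#741A6E
83,#751B6E
84,#771C6D
85,#781C6D
86,#7A1D6D
87,#7C1D6D
88,#7D1E6D
89,#7F1E6C
90,#801F6C
91,#82206C
92,#84206B
93,#85216B
94,#87216B
95,#88226A
96,#8A226A
97,#8C2369
98,#8D2369
99,#8F2469
100,#902568
101,#922568
102,#932667
103,#952667
104,#972766
105,#982766
106,#9A2865
107,#9B2964
108,#9D2964
109,#9F2A63
110,#A02A63
111,#A22B62
112,#A32C61
113,#A52C60
114,#A62D60
115,#A82E5F
116,#A92E5E
117,#AB2F5E
118,#AD305D
119,#AE305C
120,#B0315B
121,#B1325A
122,#B3325A
123,#B43359
124,#B63458
125,#B73557
126,#B93556
127,#BA3655
128,#BC3754
129,#BD3853
130,#BF3952
131,#C03A51
132,#C13A50
133,#C33B4F
134,#C43C4E
135,#C63D4D
136,#C73E4C
137,#C83F4B
138,#CA404A
139,#CB4149
140,#CC4248
141,#CE4347
142,#CF4446
143,#D04545
144,#D24644
145,#D34743
146,#D44842
147,#D54A41
148,#D74B3F
149,#D84C3E
150,#D94D3D
151,#DA4E3C
152,#DB503B
153,#DD513A
154,#DE5238
155,#DF5337
156,#E05536
157,#E15635
158,#E25734
159,#E35933
160,#E45A31
161,#E55C30
162,#E65D2F
163,#E75E2E
164,#E8602D
165,#E9612B
166,#EA632A
167,#EB6429
168,#EB6628
169,#EC6726
170,#ED6925
171,#EE6A24
172,#EF6C23
173,#EF6E21
174,#F06F20
175,#F1711F
176,#F1731D
177,#F2741C
178,#F3761B
179,#F37819
180,#F47918
181,#F57B17
182,#F57D15
183,#F67E14
184,#F68013
185,#F78212
186,#F78410
187,#F8850F
188,#F8870E
189,#F8890C
190,#F98B0B
191,#F98C0A
192,#F98E09
193,#FA9008
194,#FA9207
195,#FA9407
196,#FB9606
197,#FB9706
198,#FB9906
199,#FB9B06
200,#FB9D07
201,#FC9F07
202,#FCA108
203,#FCA309
204,#FCA50A
205,#FCA60C
206,#FCA80D
207,#FCAA0F
208,#FCAC11
209,#FCAE12
210,#FCB014
211,#FCB216
212,#FCB418
213,#FBB61A
214,#FBB81D
215,#FBBA1F
216,#FBBC21
217,#FBBE23
218,#FAC026
219,#FAC228
220,#FAC42A
221,#FAC62D
222,#F9C72F
223,#F9C932
224,#F9CB35
225,#F8CD37
226,#F8CF3A
227,#F7D13D
228,#F7D340
229,#F6D543
230,#F6D746
231,#F5D949
232,#F5DB4C
233,#F4DD4F
234,#F4DF53
235,#F4E156
236,#F3E35A
237,#F3E55D
238,#F2E661
239,#F2E865
240,#F2EA69
241,#F1EC6D
242,#F1ED71
243,#F1EF75
244,#F1F179
245,#F2F27D
246,#F2F482
247,#F3F586
248,#F3F68A
249,#F4F88E
250,#F5F992
251,#F6FA96
252,#F8FB9A
253,#F9FC9D
254,#FAFDA1
255,#FCFFA4
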