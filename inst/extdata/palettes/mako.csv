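index,hex
0,#0B0405
1,#0D0406
2,#0E0508
3,#0F0609
4,#10060A
5,#11070C
6,#12080D
7,#13090F
8,#140910
9,#150A12
10,#160B13
11,#170C15
12,#180D16
13,#190E18
14,#1A0E19
15,#1B0F1A
16,#1C101C
17,#1D111D
18,#1E111F
19,#1F1220
20,#201322
21,#211423
22,#221425
23,#231526
24,#241628
25,#251729
26,#26172B
27,#27182D
28,#28192E
29,#291930
30,#291A31
31,#2A1B33
32,#2B1C35
33,#2C1C36
34,#2D1D38
35,#2E1E39
36,#2E1E3B
37,#2F1F3D
38,#30203E
39,#312140
40,#312142
41,#322243
42,#332345
43,#342447
44,#342548
45,#35254A
46,#35264C
47,#36274D
48,#37284F
49,#372851
50,#382953
51,#382A54
52,#392B56
53,#3A2C58
54,#3A2C59
55,#3B2D5B
56,#3B2E5D
57,#3B2F5F
58,#3C3060
59,#3C3162
60,#3D3164
61,#3D3266
62,#3E3367
63,#3E3469
64,#3E356B
65,#3F366D
66,#3F366F
67,#3F3770
68,#403872
69,#403974
70,#403A76
71,#403B78
72,#403C79
73,#413D7B
74,#413E7D
75,#413E7F
76,#413F80
77,#414082
78,#414184
79,#414285
80,#414387
81,#414488
82,#40468A
83,#40478B
84,#40488D
85,#40498E
86,#3F4A8F
87,#3F4B90
88,#3F4C92
89,#3E4D93
90,#3E4F94
91,#3E5095
92,#3D5195
93,#3D5296
94,#3C5397
95,#3C5598
96,#3B5698
97,#3B5799
98,#3B589A
99,#3A599A
100,#3A5B9B
101,#3A5C9B
102,#395D9C
103,#395E9C
104,#385F9C
105,#38619D
106,#38629D
107,#38639D
108,#37649E
109,#37659E
110,#37669E
111,#37689F
112,#36699F
113,#366A9F
114,#366B9F
115,#366CA0
116,#366DA0
117,#366FA0
118,#3670A0
119,#3671A0
120,#3572A1
121,#3573A1
122,#3574A1
123,#3575A1
124,#3576A2
125,#3578A2
126,#3579A2
127,#357AA2
128,#357BA3
129,#357CA3
130,#357DA3
131,#357EA4
132,#347FA4
133,#3480A4
134,#3482A4
135,#3483A5
136,#3484A5
137,#3485A5
138,#3486A5
139,#3487A6
140,#3488A6
141,#3489A6
142,#348BA6
143,#348CA7
144,#348DA7
145,#348EA7
146,#348FA7
147,#3490A8
148,#3491A8
149,#3492A8
150,#3493A8
151,#3495A9
152,#3496A9
153,#3497A9
154,#3498A9
155,#3499AA
156,#349AAA
157,#359BAA
158,#359CAA
159,#359EAA
160,#359FAB
161,#35A0AB
162,#35A1AB
163,#36A2AB
164,#36A3AB
165,#36A4AB
166,#37A5AC
167,#37A6AC
168,#37A8AC
169,#38A9AC
170,#38AAAC
171,#39ABAC
172,#39ACAC
173,#3AADAC
174,#3AAEAD
175,#3BAFAD
176,#3CB1AD
177,#3CB2AD
178,#3DB3AD
179,#3EB4AD
180,#3FB5AD
181,#3FB6AD
182,#40B7AD
183,#41B8AD
184,#42B9AD
185,#43BAAD
186,#44BCAD
187,#45BDAD
188,#46BEAD
189,#47BFAD
190,#48C0AD
191,#49C1AD
192,#4BC2AD
193,#4CC3AD
194,#4DC4AD
195,#4FC5AD
196,#50C6AD
197,#52C7AD
198,#53C9AD
199,#55CAAD
200,#57CBAD
201,#59CCAD
202,#5BCDAD
203,#5ECDAD
204,#60CEAC
205,#62CFAC
206,#65D0AD
207,#68D1AD
208,#6AD2AD
209,#6DD3AD
210,#70D4AD
211,#73D4AD
212,#76D5AE
213,#79D6AE
214,#7CD6AF
215,#7FD7AF
216,#82D8B0
217,#85D9B1
218,#88D9B1
219,#8BDAB2
220,#8EDBB3
221,#91DBB4
222,#94DCB5
223,#96DDB5
224,#99DDB6
225,#9CDEB7
226,#9EDFB8
227,#A1DFB9
228,#A4E0BB
229,#A6E1BC
230,#A9E1BD
231,#ABE2BE
232,#AEE3C0
233,#B0E4C1
234,#B2E4C2
235,#B5E5C4
236,#B7E6C5
237,#B9E6C7
238,#BBE7C8
239,#BEE8CA
240,#C0E9CC
241,#C2E9CD
242,#C4EACF
243,#C6EBD1
244,#C8ECD2
245,#CAEDD4
246,#CCEDD6
247,#CEEED7
248,#D0EFD9
249,#D2F0DB
250,#D4F1DC
251,#D6F1DE
252,#D8F2E0
253,#DAF3E1
254,#DCF4E3
255,#DEF5E5
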