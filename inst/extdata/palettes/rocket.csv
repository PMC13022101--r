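index,hex
0,#03051A
1,#04051A
2,#05061B
3,#06071C
4,#07071D
5,#08081E
6,#0A091F
7,#0B0920
8,#0D0A21
9,#0E0B22
10,#100B23
11,#110C24
12,#130D25
13,#140E26
14,#160E27
15,#170F28
16,#180F29
17,#1A102A
18,#1B112B
19,#1D112C
20,#1E122D
21,#20122E
22,#211330
23,#221331
24,#241432
25,#251433
26,#271534
27,#281535
28,#2A1636
29,#2B1637
30,#2D1738
31,#2E1739
32,#30173A
33,#31183B
34,#33183C
35,#34193D
36,#35193E
37,#37193F
38,#381A40
39,#3A1A41
40,#3C1A42
41,#3D1A42
42,#3F1B43
43,#401B44
44,#421B45
45,#431C46
46,#451C47
47,#461C48
48,#481C48
49,#491D49
50,#4B1D4A
51,#4C1D4B
52,#4E1D4B
53,#501D4C
54,#511E4D
55,#531E4D
56,#541E4E
57,#561E4F
58,#581E4F
59,#591E50
60,#5B1E51
61,#5C1E51
62,#5E1F52
63,#601F52
64,#611F53
65,#631F53
66,#641F54
67,#661F54
68,#681F55
69,#691F55
70,#6B1F56
71,#6D1F56
72,#6E1F57
73,#701F57
74,#711F57
75,#731F58
76,#751F58
77,#761F58
78,#781F59
79,#7A1F59
80,#7B1F59
81,#7D1F5A
82,#7F1E5A
83,#811E5A
84,#821E5A
85,#841E5A
86,#861E5B
87,#871E5B
88,#891E5B
89,#8B1D5B
90,#8C1D5B
91,#8E1D5B
92,#901D5B
93,#921C5B
94,#931C5B
95,#951C5B
96,#971C5B
97,#981B5B
98,#9A1B5B
99,#9C1B5B
100,#9E1A5B
101,#9F1A5B
102,#A11A5B
103,#A3195B
104,#A4195B
105,#A6195A
106,#A8185A
107,#AA185A
108,#AB185A
109,#AD1759
110,#AF1759
111,#B01759
112,#B21758
113,#B41658
114,#B51657
115,#B71657
116,#B91657
117,#BA1656
118,#BC1656
119,#BD1655
120,#BF1654
121,#C11754
122,#C21753
123,#C41753
124,#C51852
125,#C71951
126,#C81951
127,#CA1A50
128,#CB1B4F
129,#CD1C4E
130,#CE1D4E
131,#CF1E4D
132,#D11F4C
133,#D2204C
134,#D3214B
135,#D5224A
136,#D62449
137,#D72549
138,#D82748
139,#D92847
140,#DB2946
141,#DC2B46
142,#DD2C45
143,#DE2E44
144,#DF2F44
145,#E03143
146,#E13342
147,#E23442
148,#E33641
149,#E43841
150,#E53940
151,#E63B40
152,#E73D3F
153,#E83F3F
154,#E8403E
155,#E9423E
156,#EA443E
157,#EB463E
158,#EB483E
159,#EC4A3E
160,#EC4C3E
161,#ED4E3E
162,#ED503E
163,#EE523F
164,#EE543F
165,#EF5640
166,#EF5840
167,#EF5A41
168,#F05C42
169,#F05E42
170,#F06043
171,#F16244
172,#F16445
173,#F16646
174,#F26747
175,#F26948
176,#F26B49
177,#F26D4B
178,#F26F4C
179,#F3714D
180,#F3734E
181,#F37450
182,#F37651
183,#F37852
184,#F47A54
185,#F47C55
186,#F47D57
187,#F47F58
188,#F4815A
189,#F4835B
190,#F4845D
191,#F4865E
192,#F58860
193,#F58A61
194,#F58B63
195,#F58D64
196,#F58F66
197,#F59067
198,#F59269
199,#F5946B
200,#F5966C
201,#F5976E
202,#F59970
203,#F69B71
204,#F69C73
205,#F69E75
206,#F6A077
207,#F6A178
208,#F6A37A
209,#F6A47C
210,#F6A67E
211,#F6A880
212,#F6A981
213,#F6AB83
214,#F6AD85
215,#F6AE87
216,#F6B089
217,#F6B18B
218,#F6B38D
219,#F6B48F
220,#F6B691
221,#F6B893
222,#F6B995
223,#F6BB97
224,#F6BC99
225,#F6BE9B
226,#F6BF9D
227,#F6C19F
228,#F7C2A2
229,#F7C4A4
230,#F7C6A6
231,#F7C7A8
232,#F7C9AA
233,#F7CAAC
234,#F7CCAF
235,#F7CDB1
236,#F7CFB3
237,#F7D0B5
238,#F8D1B8
239,#F8D3BA
240,#F8D4BC
241,#F8D6BE
242,#F8D7C0
243,#F8D9C3
244,#F8DAC5
245,#F8DCC7
246,#F9DDC9
247,#F9DFCB
248,#F9E0CD
249,#F9E2D0
250,#F9E3D2
251,#F9E5D4
252,#FAE6D6
253,#FAE8D8
254,#FAE9DA
255,#FAEBDD
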