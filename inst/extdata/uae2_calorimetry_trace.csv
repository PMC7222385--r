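time_s,temperature_C
0,20.0685
1,20.1609
2,20.3964
3,20.599
4,20.7766
5,20.9402
6,21.2102
7,21.319
8,21.6137
9,21.6988
10,21.9563
11,22.1945
12,22.1998
13,22.4444
14,22.6408
15,22.8683
16,23.0114
17,23.0819
18,23.2818
19,23.659
20,23.7667
21,23.8821
22,24.1517
23,24.4101
24,24.6332
25,24.706
26,24.9038
27,25.0176
28,25.3179
29,25.452
30,25.6958
31,25.8974
32,26.103
33,26.2099
34,26.4547
35,26.5327
36,26.7685
37,26.9542
38,27.0652
39,27.3768
40,27.5744
41,27.7352
42,27.9802
43,28.0951
44,28.2521
45,28.5313
46,28.6581
47,28.96
48,29.0553
49,29.2988
50,29.4712
51,29.605
52,29.9121
53,30.0546
54,30.216
55,30.4145
56,30.6237
57,30.7833
58,30.8183
59,31.1713
60,31.3278
61,31.5445
62,31.7534
63,31.9834
64,32.0662
65,32.3568
66,32.4976
67,32.7218
68,32.905
69,33.0841
70,33.185
71,33.4218
72,33.6466
73,33.7568
74,33.9664
75,34.2117
76,34.4102
77,34.5841
78,34.7057
79,34.8841
80,35.2038
81,35.3302
82,35.5108
83,35.6895
84,35.8249
85,36.1043
86,36.252
87,36.4428
88,36.6877
89,36.8712
90,37.0888
91,37.1845
92,37.4299
93,37.6561
94,37.7201
95,37.9217
96,38.0973
97,38.27
98,38.536
99,38.7538
100,38.9703
101,39.1516
102,39.2383
103,39.57
104,39.6333
105,39.861
106,40.0238
107,40.2279
108,40.4325
109,40.6181
110,40.8
111,40.9958
112,41.1552
113,41.3434
114,41.4746
115,41.7277
116,41.9103
117,42.2601
118,42.246
119,42.5101
120,42.6176
121,42.8079
122,43.0767
123,43.2098
124,43.4486
125,43.6164
126,43.7962
127,43.9148
128,44.1439
129,44.4032
130,44.6117
131,44.7478
132,44.9615
133,45.2068
134,45.4117
135,45.474
136,45.7121
137,45.9671
138,46.0727
139,46.2826
140,46.47
141,46.6191
142,46.8303
143,47.0402
144,47.2101
145,47.4755
146,47.5849
147,47.7764
148,48.022
149,48.1235
150,48.3633
151,48.4769
152,48.8019
153,48.919
154,49.0984
155,49.249
156,49.4996
157,49.6491
158,49.8515
159,50.1317
160,50.2476
161,50.3919
162,50.6428
163,50.8056
164,51.0423
165,51.2735
166,51.3414
167,51.6029
168,51.7735
169,52.0031
170,52.1359
171,52.3784
172,52.4384
173,52.7992
174,52.9471
175,53.0854
176,53.2096
177,53.5033
178,53.6844
179,53.849
180,54.046
181,54.1984
182,54.4351
183,54.6205
184,54.7809
185,54.9172
186,55.2081
187,55.3899
188,55.5095
189,55.6606
190,55.9397
191,56.1013
192,56.3203
193,56.4321
194,56.6379
195,56.9293
196,57.0843
197,57.2825
198,57.5331
199,57.6378
200,57.7205
201,58.0263
202,58.2573
203,58.4908
204,58.5081
205,58.7085
206,58.9198
207,59.0915
208,59.301
209,59.5132
210,59.6515
211,60.0025
212,60.0951
213,60.2746
214,60.4927
215,60.6589
216,60.8395
217,61.1091
218,61.2135
219,61.3493
220,61.6218
221,61.7741
222,61.9547
223,62.1165
224,62.3804
225,62.5394
226,62.763
227,62.9146
228,63.0825
229,63.367
230,63.48
231,63.7301
232,63.8117
233,64.0376
234,64.2365
235,64.4195
236,64.6956
237,64.8162
238,65.0186
239,65.1484
240,65.3481
241,65.6236
242,65.8257
243,66.0144
244,66.072
245,66.4326
246,66.5701
247,66.707
248,66.9326
249,67.038
250,67.2208
251,67.4672
252,67.5939
253,67.8524
254,68.0969
255,68.1694
256,68.3733
257,68.6017
258,68.7376
259,68.9584
260,69.2103
261,69.4042
262,69.5641
263,69.6414
264,69.9204
265,70.1654
266,70.3419
267,70.4808
268,70.5445
269,70.8716
270,71.0864
271,71.2491
272,71.4438
273,71.6466
274,71.7943
275,72.0687
276,72.2158
277,72.3193
278,72.6396
279,72.8198
280,72.9899
281,73.0547
282,73.2984
283,73.5478
284,73.7073
285,73.9116
286,74.2063
287,74.2315
288,74.3559
289,74.6643
290,74.8054
291,75.0511
292,75.1773
293,75.5176
294,75.59
295,75.7614
296,75.966
297,76.2066
298,76.3574
299,76.4604
300,76.7305
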