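record,actual,tp,fp,fn
100,2273,2272,0,1
101,1865,1865,3,0
102,2187,2187,0,0
103,2084,2082,1,2
104,2229,2229,16,0
105,2572,2572,44,0
106,2027,2021,1,6
107,2137,2132,1,5
108,1763,1763,41,0
109,2532,2527,1,5
111,2124,2122,1,2
112,2539,2538,1,1
113,1795,1794,0,1
114,1879,1879,6,0
115,1953,1952,1,1
116,2412,2401,3,11
117,1535,1534,1,1
118,2278,2277,1,1
119,1987,1986,2,1
121,1863,1861,1,2
122,2476,2475,1,1
123,1518,1514,1,4
124,1619,1618,1,1
200,2601,2600,2,1
201,1963,1944,6,19
202,2136,2128,3,8
203,2980,2964,14,16
205,2656,2651,1,5
207,2332,2260,12,72
208,2955,2945,3,10
209,3005,3005,1,0
210,2650,2601,3,49
212,2748,2747,1,1
213,3251,3243,0,8
214,2262,2260,1,2
215,3363,3359,1,4
217,2208,2203,1,5
219,2154,2152,2,2
220,2048,2047,1,1
221,2427,2404,1,23
222,2483,2479,2,4
223,2605,2583,1,22
228,2053,2053,10,0
230,2256,2255,1,1
231,1571,1570,1,1
232,1780,1780,139,0
233,3079,3071,1,8
234,2753,2748,1,5
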