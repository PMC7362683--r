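cohort,c52,c55,c59,c63,c67,c71,c75,c81,c86
12,1663,1460,0,0,0,0,0,0,0
11,0,2008,1803,0,0,0,0,0,0
10,0,0,1508,1344,0,0,0,0,0
9,2804,2598,0,2473,2345,0,0,0,0
8,0,2447,2288,0,1987,1921,0,0,0
7,0,0,2023,1891,0,1536,1407,0,0
6,0,0,0,1674,1584,0,1216,1077,0
5,0,0,0,0,1348,1283,0,1556,1468
4,0,0,0,0,0,1339,1305,0,393
3,0,0,0,0,0,0,688,640,0
2,0,0,0,0,0,0,0,696,667
1,0,0,0,0,0,0,0,0,11
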