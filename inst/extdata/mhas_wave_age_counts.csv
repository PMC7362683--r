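wave,c52,c55,c59,c63,c67,c71,c75,c81,c86
2001,2804,2447,2023,1674,1348,1339,688,696,11
2003,0,2598,2288,1891,1584,1283,1305,640,667
2012,1663,2008,1508,2473,1987,1536,1216,1556,393
2015,0,1460,1803,1344,2345,1921,1407,1077,1468
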