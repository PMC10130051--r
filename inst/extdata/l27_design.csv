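run,co2,led,ec,day_temp,night_temp,humidity
1,1,1,1,1,1,1
2,1,1,1,1,2,2
3,1,1,1,1,3,3
4,1,2,2,2,1,1
5,1,2,2,2,2,2
6,1,2,2,2,3,3
7,1,3,3,3,1,1
8,1,3,3,3,2,2
9,1,3,3,3,3,3
10,2,1,2,3,1,2
11,2,1,2,3,2,3
12,2,1,2,3,3,1
13,2,2,3,1,1,2
14,2,2,3,1,2,3
15,2,2,3,1,3,1
16,2,3,1,2,1,2
17,2,3,1,2,2,3
18,2,3,1,2,3,1
19,3,1,3,2,1,3
20,3,1,3,2,2,1
21,3,1,3,2,3,2
22,3,2,1,3,1,3
23,3,2,1,3,2,1
24,3,2,1,3,3,2
25,3,3,2,1,1,3
26,3,3,2,1,2,1
27,3,3,2,1,3,2
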