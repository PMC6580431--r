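day,n_scanned,n_marked,with_replacement
1,67,1,0
2,236,2,0
3,307,0,0
4,305,0,0
5,382,2,0
6,476,4,0
7,519,5,0
8,606,6,0
9,678,2,0
10,610,4,0
11,598,2,0
12,687,1,0
13,796,3,0
14,905,7,0
15,819,1,0
16,782,2,0
17,778,4,0
18,739,2,0
19,813,5,0
20,869,6,0
21,878,4,0
22,894,3,0
23,778,3,0
24,785,4,0
25,773,6,0
26,767,4,0
27,771,3,0
28,695,4,0
29,769,1,0
30,745,5,0
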