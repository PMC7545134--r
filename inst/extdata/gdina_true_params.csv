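item,subset,delta
1,0,0.10
1,1,0.70
2,0,0.10
2,1,0.70
3,0,0.10
3,1,0.70
4,0,0.10
4,1,0.70
5,0,0.10
5,1,0.70
6,0,0.10
6,1,0.70
7,0,0.10
7,1,0.70
8,0,0.10
8,1,0.70
9,0,0.10
9,1,0.70
10,0,0.10
10,1,0.70
11,0,0.10
11,1,0.70
12,0,0.10
12,1,0.70
13,0,0.20
13,1,0.10
13,2,0.15
13,12,0.40
14,0,0.20
14,1,0.10
14,2,0.15
14,12,0.40
15,0,0.20
15,1,0.10
15,2,0.15
15,12,0.40
16,0,0.20
16,1,0.10
16,2,0.15
16,12,0.40
17,0,0.20
17,1,0.10
17,2,0.15
17,12,0.40
18,0,0.20
18,1,0.30
18,2,0.30
18,12,-0.05
19,0,0.20
19,1,0.30
19,2,0.30
19,12,-0.05
20,0,0.20
20,1,0.30
20,2,0.30
20,12,-0.05
21,0,0.20
21,1,0.20
21,2,0.20
21,12,0.00
22,0,0.20
22,1,0.20
22,2,0.20
22,12,0.00
23,0,0.20
23,1,0.20
23,2,0.20
23,12,0.00
24,0,0.20
24,1,0.20
24,2,0.20
24,12,0.00
25,0,0.20
25,1,0.10
25,2,0.10
25,3,0.10
25,12,0.05
25,13,-0.05
25,23,0.05
25,123,0.15
26,0,0.20
26,1,0.10
26,2,0.10
26,3,0.10
26,12,0.10
26,13,0.10
26,23,0.05
26,123,0.05
27,0,0.20
27,1,0.10
27,2,0.10
27,3,0.10
27,12,0.05
27,13,-0.05
27,23,0.05
27,123,0.15
28,0,0.20
28,1,0.10
28,2,0.10
28,3,0.10
28,12,0.05
28,13,-0.05
28,23,0.05
28,123,0.15
29,0,0.20
29,1,0.10
29,2,0.10
29,3,0.10
29,12,0.10
29,13,0.10
29,23,0.05
29,123,0.05
30,0,0.20
30,1,0.10
30,2,0.10
30,3,0.10
30,12,0.05
30,13,-0.05
30,23,0.05
30,123,0.15
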