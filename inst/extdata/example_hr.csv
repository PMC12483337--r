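t,bpm
0,80.1
1,80.6
2,80.2
3,81.6
4,82.2
5,81
6,83.2
7,82.7
8,81.7
9,81.9
10,82.6
11,82.9
12,82.7
13,82.5
14,82.9
15,83.5
16,0
17,83.1
18,83.5
19,84.4
20,85.7
21,86.3
22,85.9
23,85.5
24,85.9
25,86
26,84.3
27,86.2
28,86.2
29,
30,84.9
31,85.4
32,86.9
33,87.4
34,85.8
35,86.3
36,87.2
37,87.2
38,86.9
39,87
40,87.4
41,87.7
42,0
43,89.2
44,89.2
45,89.4
46,89.4
47,88.6
48,88.8
49,90
50,89.7
51,90.2
52,90.2
53,90.4
54,90
55,90.6
56,91.1
57,90.6
58,90.4
59,90
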