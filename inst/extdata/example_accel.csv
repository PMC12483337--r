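t,acc_x,acc_y,acc_z
0,0.67,-1.7,512.55
1,-0.54,1.91,508.74
2,2.73,1.17,517.03
3,-3.32,-1.44,515.6
4,-0.57,6.6,512.36
5,2.42,0.19,517.63
6,4.41,-0.64,508.37
7,3.09,1.41,518.16
8,1.3,-0.25,508.24
9,-0.28,-1.98,517.1
10,-1.4,-1.07,512.68
11,0.9,-3.64,510.28
12,3.53,3.37,514.5
13,-0.32,3.3,513.86
14,0.86,-7.76,514.33
15,-3.62,-3.13,506.4
16,-3.62,-1.25,510.94
17,0.22,3.31,512.04
18,2.27,5.13,511.47
19,1.91,-0.01,511.65
20,-1.7,0.49,505.54
21,2.18,-2.2,517.14
22,0.65,-7.06,503.57
23,-2.57,4.01,516.84
24,2.2,3.82,513.82
25,-2.07,11.24,516.48
26,-4.83,-11.18,505.4
27,3.41,-7.36,509.84
28,1.34,-4.71,515.25
29,-5.93,2.86,515.51
30,-0.99,5.42,511.48
31,-0.45,-1.4,517.81
32,0,-2.82,509.48
33,3.65,6.45,503.7
34,5.44,2.9,512.03
35,-2.46,-4.81,507.67
36,-0.66,0.74,519.06
37,-6.12,3.51,508.59
38,4.49,-2.04,515.77
39,1.66,0.56,510.4
40,-3.64,5.32,516.6
41,-0.9,1.74,513.71
42,5.7,-4.02,513.69
43,3.35,5.34,505.35
44,-0.79,-6.35,509.1
45,1.41,-0.26,509.37
46,0.36,-8.15,511.27
47,0.02,5.4,509.52
48,-0.42,-3.33,513.81
49,4.29,2.93,515.24
50,1.62,-5.67,508.75
51,-0.94,-0.75,514.7
52,0.91,-1.31,512.92
53,-1.01,2.31,514.53
54,-2.13,-0.06,511.47
55,0.17,5.42,505.46
56,2.17,-1.76,510.43
57,-4.14,-2.97,514.35
58,-0.96,-3.71,512.72
59,5.27,-1.03,512.98
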