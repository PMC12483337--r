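beat_time,rr_ms
0.767,767.1
1.53,763.2
2.289,758.7
3.052,763.3
3.811,758.3
4.563,752.7
5.314,750.2
6.06,746.6
6.808,747.6
7.548,740.7
8.285,737
9.026,741
9.763,737
10.5,736.6
11.235,734.7
11.96,725.1
12.671,711
13.383,712.4
14.092,709
14.802,709.7
15.505,703.2
16.208,703.1
16.909,701.1
17.607,698
18.305,697.8
19.003,697.4
19.701,698.8
20.395,693.6
21.084,689.6
21.778,693.5
22.469,690.8
23.159,689.9
23.852,693.5
24.553,700.6
25.259,706.5
25.965,705.5
26.672,706.9
27.377,705.3
28.079,702.3
28.782,702.7
29.486,704.5
30.182,695.3
30.881,698.8
31.578,696.9
32.278,700.8
32.977,698.7
33.671,694.3
34.365,694.2
35.055,689.7
35.746,691.1
36.438,691.2
37.124,686
37.807,683.7
38.497,689.7
39.184,686.9
39.868,683.8
40.55,682
41.233,683.2
41.916,683.2
42.592,676.5
43.27,677.3
43.944,674.6
44.619,674.5
45.295,676.2
45.961,666.1
46.628,666.8
47.298,670
47.967,668.5
48.639,672.7
49.312,672.8
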