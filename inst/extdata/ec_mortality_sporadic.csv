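"age","rate_per_1000py"
40,26.4
41,27.86
42,29.32
43,30.78
44,32.24
45,33.7
46,35.16
47,36.62
48,38.08
49,39.54
50,41
51,42.46
52,43.92
53,45.38
54,46.84
55,48.3
56,49.76
57,51.22
58,52.68
59,54.14
60,55.6
61,57.06
62,58.52
63,59.98
64,61.44
65,62.9
66,64.36
67,65.82
68,67.28
69,68.74
70,70.2
71,71.66
72,73.12
73,74.58
74,76.04
75,77.5
76,78.96
77,80.42
78,81.88
79,83.34
80,84.8
81,86.26
82,87.72
83,89.18
84,90.64
85,92.1
86,92.1
87,92.1
88,92.1
89,92.1
90,92.1
91,92.1
92,92.1
93,92.1
94,92.1
95,92.1
96,92.1
97,92.1
98,92.1
99,92.1
100,92.1
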