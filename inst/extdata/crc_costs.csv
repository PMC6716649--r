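"age","stage1","stage2","stage3","stage4"
25,14000,22000,32000,38000
26,14000,22000,32000,38000
27,14000,22000,32000,38000
28,14000,22000,32000,38000
29,14000,22000,32000,38000
30,14000,22000,32000,38000
31,14000,22000,32000,38000
32,14000,22000,32000,38000
33,14000,22000,32000,38000
34,14000,22000,32000,38000
35,14000,22000,32000,38000
36,14000,22000,32000,38000
37,14000,22000,32000,38000
38,14000,22000,32000,38000
39,14000,22000,32000,38000
40,14000,22000,32000,38000
41,14000,22000,32000,38000
42,14000,22000,32000,38000
43,14000,22000,32000,38000
44,14000,22000,32000,38000
45,14000,22000,32000,38000
46,14000,22000,32000,38000
47,14000,22000,32000,38000
48,14000,22000,32000,38000
49,14000,22000,32000,38000
50,14000,22000,32000,38000
51,14000,22000,32000,38000
52,14000,22000,32000,38000
53,14000,22000,32000,38000
54,14000,22000,32000,38000
55,14000,22000,32000,38000
56,14000,22000,32000,38000
57,14000,22000,32000,38000
58,14000,22000,32000,38000
59,14000,22000,32000,38000
60,14000,22000,32000,38000
61,13944,21912,31872,37848
62,13888,21824,31744,37696
63,13832,21736,31616,37544
64,13776,21648,31488,37392
65,13720,21560,31360,37240
66,13664,21472,31232,37088
67,13608,21384,31104,36936
68,13552,21296,30976,36784
69,13496,21208,30848,36632
70,13440,21120,30720,36480
71,13384,21032,30592,36328
72,13328,20944,30464,36176
73,13272,20856,30336,36024
74,13216,20768,30208,35872
75,13160,20680,30080,35720
76,13104,20592,29952,35568
77,13048,20504,29824,35416
78,12992,20416,29696,35264
79,12936,20328,29568,35112
80,12880,20240,29440,34960
81,12824,20152,29312,34808
82,12768,20064,29184,34656
83,12712,19976,29056,34504
84,12656,19888,28928,34352
85,12600,19800,28800,34200
86,12544,19712,28672,34048
87,12488,19624,28544,33896
88,12432,19536,28416,33744
89,12376,19448,28288,33592
90,12320,19360,28160,33440
91,12264,19272,28032,33288
92,12208,19184,27904,33136
93,12152,19096,27776,32984
94,12096,19008,27648,32832
95,12040,18920,27520,32680
96,11984,18832,27392,32528
97,11928,18744,27264,32376
98,11872,18656,27136,32224
99,11816,18568,27008,32072
100,11760,18480,26880,31920
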