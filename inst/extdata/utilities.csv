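"age","female","male"
25,0.95,0.96
26,0.947792,0.957792
27,0.945568,0.955568
28,0.943328,0.953328
29,0.941072,0.951072
30,0.9388,0.9488
31,0.936512,0.946512
32,0.934208,0.944208
33,0.931888,0.941888
34,0.929552,0.939552
35,0.9272,0.9372
36,0.924832,0.934832
37,0.922448,0.932448
38,0.920048,0.930048
39,0.917632,0.927632
40,0.9152,0.9252
41,0.912752,0.922752
42,0.910288,0.920288
43,0.907808,0.917808
44,0.905312,0.915312
45,0.9028,0.9128
46,0.900272,0.910272
47,0.897728,0.907728
48,0.895168,0.905168
49,0.892592,0.902592
50,0.89,0.9
51,0.887392,0.897392
52,0.884768,0.894768
53,0.882128,0.892128
54,0.879472,0.889472
55,0.8768,0.8868
56,0.874112,0.884112
57,0.871408,0.881408
58,0.868688,0.878688
59,0.865952,0.875952
60,0.8632,0.8732
61,0.860432,0.870432
62,0.857648,0.867648
63,0.854848,0.864848
64,0.852032,0.862032
65,0.8492,0.8592
66,0.846352,0.856352
67,0.843488,0.853488
68,0.840608,0.850608
69,0.837712,0.847712
70,0.8348,0.8448
71,0.831872,0.841872
72,0.828928,0.838928
73,0.825968,0.835968
74,0.822992,0.832992
75,0.82,0.83
76,0.816992,0.826992
77,0.813968,0.823968
78,0.810928,0.820928
79,0.807872,0.817872
80,0.8048,0.8148
81,0.801712,0.811712
82,0.798608,0.808608
83,0.795488,0.805488
84,0.792352,0.802352
85,0.7892,0.7992
86,0.786032,0.796032
87,0.782848,0.792848
88,0.779648,0.789648
89,0.776432,0.786432
90,0.7732,0.7832
91,0.769952,0.779952
92,0.766688,0.776688
93,0.763408,0.773408
94,0.760112,0.770112
95,0.7568,0.7668
96,0.753472,0.763472
97,0.750128,0.760128
98,0.746768,0.756768
99,0.743392,0.753392
100,0.74,0.75
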