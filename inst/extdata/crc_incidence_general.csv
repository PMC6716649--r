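"age","rate"
25,0.000164475053496458
26,0.000175521037624818
27,0.000187308859270602
28,0.000199888339517732
29,0.000213312645385519
30,0.000227638514538422
31,0.000242926495087089
32,0.000259241201494209
33,0.000276651587666746
34,0.000295231238388783
35,0.00031505868032671
36,0.000336217713921224
37,0.000358797767568857
38,0.000382894275590007
39,0.000408609081580924
40,0.00043605086885442
41,0.000465335619788563
42,0.000496587106024776
43,0.00052993741158717
44,0.000565527491134048
45,0.000603507765701051
46,0.000644038758453818
47,0.000687291773137183
48,0.000733449618088358
49,0.00078270737887413
50,0.000835273242817626
51,0.000891369378899478
52,0.000951232876752311
53,0.00101511674871717
54,0.00108329099919706
55,0.00115604376582732
56,0.00123368253728571
57,0.00131653545288963
58,0.0014049526894729
59,0.00149930794140385
60,0.0016
61,0.00170745443901471
62,0.00182212541331939
63,0.00194449757838357
64,0.00207508813866523
65,0.0022144490335692
66,0.00236316927021223
67,0.00252187741285439
68,0.00269124423951822
69,0.00287198557702384
70,0.00306486532642223
71,0.00327069869161369
72,0.00349035562479712
73,0.00372476450331238
74,0.00397491605341571
75,0.00424186753757217
76,0.0045267472229625
77,0.00483075915009051
78,0.0051551882216456
79,0.0055014056331282
80,0.00587087466819079
81,0.00626515688318836
82,0.0066859187070772
83,0.00713493848455652
84,0.00761411399222057
85,0.00812547045948813
86,0.00867116912820993
87,0.00925351638713084
88,0.00987497351981369
89,0.0105381671072241
90,0.0112459001289429
91,0.0120011638099247
92,0.0128071502628742
93,0.0136672659796705
94,0.0145851462288645
95,0.0155646704200958
96,0.016609978500371
97,0.0177254884514983
98,0.0189159149626342
99,0.020186289356859
100,0.0215419808560027
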