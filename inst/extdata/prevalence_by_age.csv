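"age","prevalence"
40,0.14131475066646
41,0.133031954280486
42,0.125163868602081
43,0.117697960166978
44,0.110621074678539
45,0.1039195864986
46,0.0975795356167164
47,0.0915867518975657
48,0.0859269666626072
49,0.0805859118738619
50,0.0755494073573527
51,0.0708034366347898
52,0.0663342120284051
53,0.0621282297696419
54,0.0581723158819511
55,0.0544536636253683
56,0.0509598632897592
57,0.0476789251082286
58,0.0445992960354095
59,0.0417098711000558
60,0.039
61,0.0364594895622137
62,0.0340786026431467
63,0.0318480539961578
64,0.0297590035847992
65,0.0278030477738698
66,0.0259722087851598
67,0.0242589227621517
68,0.0226560267479336
69,0.0211567448434179
70,0.0197546737787267
71,0.0184437680993147
72,0.0172183251400025
73,0.0160729699344755
74,0.0150026401848492
75,0.0140025713954375
76,0.0130682822567297
77,0.0121955603495991
78,0.0113804482257538
79,0.0106192299082276
80,0.00990841784511748
81,0.00924474034064573
82,0.00862512947980926
83,0.00804670955622374
84,0.00750678600715422
85,0.00700283485501759
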