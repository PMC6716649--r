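"age","weight"
40,3.82086736303217e-05
41,0.000122427296460934
42,0.000313125837684702
43,0.000679079796324273
44,0.00129839644629099
45,0.00224767529175124
46,0.00359038798258135
47,0.00536680971889277
48,0.00758716233800563
49,0.0102287643233524
50,0.0132371743227342
51,0.0165307061470505
52,0.0200073350239151
53,0.0235528921343256
54,0.0270495060440441
55,0.0303834317713039
56,0.0334516501974779
57,0.0361668732629473
58,0.0384608195906735
59,0.0402858108326486
60,0.041614873005371
61,0.0424406099503612
62,0.0427731539876694
63,0.042637500898502
64,0.0420705125270693
65,0.0411178299677191
66,0.0398308916016345
67,0.03826419955496
68,0.0364729300822433
69,0.0345109409239261
70,0.0324291934629736
71,0.0302745800630895
72,0.0280891270866001
73,0.0259095310349285
74,0.0237669780133263
75,0.0216871941631817
76,0.0196906757061351
77,0.0177930507694602
78,0.0160055303130218
79,0.0143354115133799
80,0.0127866032990652
81,0.0113601499413695
82,0.0100547343881586
83,0.00886714819634013
84,0.00779271937292329
85,0.00682569314449546
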