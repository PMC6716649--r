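"age","female","male"
0,2e-04,0.00025
1,2e-04,0.00025
2,2e-04,0.00025
3,2e-04,0.00025
4,2e-04,0.00025
5,2e-04,0.00025
6,2e-04,0.00025
7,2e-04,0.00025
8,2e-04,0.00025
9,2e-04,0.00025
10,2e-04,0.00025
11,2e-04,0.00025
12,2e-04,0.00025
13,2e-04,0.00025
14,2e-04,0.00025
15,0.000204593053522148,0.00025
16,0.000210395019914092,0.000250658366523487
17,0.000216813599809797,0.000261355999682995
18,0.000223914324821708,0.000273190541369513
19,0.00023176969104197,0.000286282818403283
20,0.000240459899203943,0.000300766498673238
21,0.000250073673505596,0.00031678945584266
22,0.0002607091674547,0.000334515279091167
23,0.00027247496598421,0.000354124943307017
24,0.000285491194069101,0.000375818656781836
25,0.000299890743163282,0.000399817905272136
26,0.000315820627978099,0.000426367713296832
27,0.000333443487454714,0.000455739145757856
28,0.000352939245254771,0.000488232075424619
29,0.000374506946722452,0.00052417824453742
30,0.000398366791072674,0.00056394465178779
31,0.000424762379553436,0.000607937299255726
32,0.000453963202535302,0.000656605337558837
33,0.000486267390920409,0.000710445651534015
34,0.000522004759961979,0.000770007933269964
35,0.000561540176570746,0.000835900294284577
36,0.000605277284487411,0.000908795474145686
37,0.000653662625353904,0.000989437708923174
38,0.000707190197758267,0.00107865032959711
39,0.000766406500799513,0.00117734416799919
40,0.000831916113665628,0.00128652685610938
41,0.000904387868190376,0.00140731311365063
42,0.000984561677408718,0.00154093612901453
43,0.00107325608982817,0.00168876014971361
44,0.00117137664654273,0.00185229441090455
45,0.00127992512651288,0.00203320854418814
46,0.00140000977440278,0.00223334962400464
47,0.00153285661539776,0.00245476102566294
48,0.00167982197252257,0.00269970328753762
49,0.00184240631425817,0.00297067719043028
50,0.00202226957383674,0.0032704492897279
51,0.00222124809661995,0.00360208016103324
52,0.0024413733885876,0.003968955647646
53,0.00268489285735276,0.00437482142892127
54,0.0029542927574623,0.00482382126243717
55,0.00325232357424689,0.00532053929041148
56,0.00358202810538135,0.00587004684230225
57,0.00394677252685896,0.0064779542114316
58,0.00435028076055316,0.00715046793425527
59,0.00479667249424827,0.00789445415708045
60,0.00529050524231145,0.00871750873718574
61,0.00583682087643158,0.00962803479405264
62,0.00644119710148886,0.0106353285024814
63,0.00710980440210688,0.0117496740035115
64,0.00784946904129309,0.0129824484021551
65,0.00866774275436316,0.0143462379239386
66,0.00957297984970161,0.0158549664161694
67,0.0105744225035323,0.0175240375058872
68,0.0116822951195308,0.0193704918658846
69,0.0129079087166592,0.0214131811944321
70,0.0142637764109901,0.0236729606849835
71,0.0157637411705499,0.0261729019509166
72,0.0174231171475193,0.0289385285791988
73,0.0192588460307438,0.0319980767179064
74,0.0212896700148656,0.0353827833581094
75,0.0235363231520325,0.0391272052533875
76,0.0260217430398247,0.0432695717330411
77,0.0287713050066635,0.0478521750111058
78,0.0318130811856583,0.0529218019760972
79,0.0351781271219527,0.0585302118699212
80,0.0389007988397362,0.0647346647328936
81,0.0430191036060733,0.0715985060101222
82,0.047575087972735,0.0791918132878917
83,0.0526152670578123,0.0875921117630205
84,0.0581910994499377,0.0968851657498962
85,0.064359512583734,0.107165854306223
86,0.0711834839503995,0.118539139917333
87,0.0787326840774041,0.131121140129007
88,0.0870841878419066,0.145040313069844
89,0.0963232613801751,0.160438768966959
90,0.106544232627096,0.17747372104516
91,0.1178514543737,0.196319090622834
92,0.130360369675208,0.217167282792013
93,0.144198690487063,0.240231150811772
94,0.159507701562447,0.265746169270745
95,0.176443702923642,0.293972838206069
96,0.195179605634405,0.325199342724008
97,0.215906697165674,0.359744495276124
98,0.23883659437841,0.397960990630684
99,0.264203404062896,0.440239006771493
100,0.292266113092901,0.487010188488168
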