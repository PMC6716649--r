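"age","MLH1","MSH2","MSH6","PMS2"
40,0.251739302518344,0.283545899657801,0.40832826938888,0.0563865284349744
41,0.242898722607742,0.284175613174945,0.414975991681322,0.0579496725359918
42,0.234179221227675,0.284723376744009,0.421560735578982,0.0595366664493341
43,0.225592246769774,0.285187247347045,0.428073757539427,0.0611467483437537
44,0.217148560099547,0.285565653335468,0.434506636409823,0.0627791501551628
45,0.208858181711537,0.285857397038419,0.440851317429408,0.064433103820636
46,0.20073034758228,0.28606165360697,0.447100151509561,0.0661078473011898
47,0.192773474007033,0.286177966244382,0.453245929433205,0.0678026303153803
48,0.184995131532524,0.286206238031322,0.459281910721988,0.0695167197141647
49,0.177402027930483,0.28614672060584,0.465201847026621,0.0712494044370558
50,0.17,0.286,0.471,0.073
51,0.162794013844414,0.28576697996781,0.476671153711482,0.0747678524762935
52,0.15578817314345,0.285448863162156,0.482210621751511,0.076552341942883
53,0.148985734835823,0.285047130531978,0.487614249256946,0.0783528853752536
54,0.142389131542833,0.284563519315346,0.492878410157307,0.0801689389845133
55,0.136,0.284,0.498,0.082
56,0.130499439356735,0.284380900892062,0.501520047869385,0.0835996118818183
57,0.12516029983968,0.28469894183744,0.504931987413179,0.0852087709097008
58,0.119982660489378,0.284954998482123,0.508235221533593,0.0868271194949055
59,0.11496617772872,0.28515007348696,0.511429421703484,0.0884543270808368
60,0.11011011011011,0.285285285285285,0.514514514514514,0.0900900900900901
61,0.10537186495359,0.286735729647172,0.516420150404271,0.0914722549949676
62,0.100793606912179,0.288131833478094,0.518220045331523,0.0928545142782041
63,0.096373613055223,0.289474136658184,0.519915583424081,0.094236666862512
64,0.0921098495204832,0.290763280800381,0.521508327264738,0.0956185424143978
65,0.088,0.292,0.523,0.097
66,0.0838875417777429,0.294684830070214,0.523797365922597,0.0976302622294459
67,0.0799346225848008,0.297327018401234,0.524493232662883,0.0982451263510823
68,0.0761380397760356,0.299926745838797,0.525090368138268,0.0988448462468992
69,0.0724943698619211,0.302484286665349,0.525591640816605,0.099429702656125
70,0.069,0.305,0.526,0.1
71,0.0652718119946961,0.308351131217146,0.52591895336561,0.100458103422548
72,0.061718369513067,0.311658445848633,0.525726394966149,0.100896789672151
73,0.0583342916612988,0.314922279833888,0.525426802776932,0.101316625727882
74,0.0551140584596363,0.318143065857242,0.52502467882385,0.101718196859272
75,0.0520520520520521,0.321321321321321,0.524524524524525,0.102102102102102
76,0.0491640060083234,0.324927692334576,0.523593153572691,0.10231514808441
77,0.046420261378821,0.328498377634862,0.522570572793242,0.102510788193075
78,0.0438153211302987,0.332033719628665,0.521461262549275,0.102689696691761
79,0.0413437102611642,0.335534113709259,0.520269630818314,0.102852545211263
80,0.039,0.339,0.519,0.103
81,0.0367788290727452,0.342431855697006,0.517656595721231,0.103132719509019
82,0.0346749221970229,0.345830188012645,0.516243537497352,0.10325135229298
83,0.0326831059746889,0.349195527713462,0.514764831104583,0.103356535207266
84,0.0307983223615892,0.352528423239657,0.513224362518274,0.10344889188048
85,0.0290156398974058,0.355829435387987,0.511625893273376,0.103529031441231
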