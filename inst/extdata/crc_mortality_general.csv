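"age","early","late"
25,0.0317109640373421,0.453470244873435
26,0.0320296645243174,0.457112556653902
27,0.0323515680044367,0.460784123794024
28,0.0326767066683161,0.464485181275349
29,0.033005113030093,0.468215965966821
30,0.0333368199306773,0.471976716639932
31,0.0336718605410354,0.47576767398401
32,0.0340102683655076,0.479589080621619
33,0.0343520772451584,0.483441181124088
34,0.0346973213611605,0.487324222027163
35,0.0350460352382132,0.491238451846789
36,0.0353982537479949,0.495184121095009
37,0.03575401211265,0.499161482296003
38,0.0361133459083115,0.503170790002244
39,0.0364762910686584,0.507212300810795
40,0.0368428838885092,0.511286273379727
41,0.0372131610274513,0.515392968444674
42,0.0375871595135072,0.519532648835523
43,0.0379649167468373,0.523705579493232
44,0.0383464705034795,0.527912027486786
45,0.0387318589391276,0.532152262030294
46,0.0391211205929463,0.536426554500214
47,0.0395142943914253,0.540735178452723
48,0.0399114196522721,0.545078409641224
49,0.0403125360883438,0.549456526033995
50,0.0407176838116182,0.553869807831981
51,0.0411269033372053,0.558318537486723
52,0.0415402355873986,0.562802999718438
53,0.0419577218957677,0.567323481534238
54,0.0423794040112912,0.571880272246503
55,0.0428053241025321,0.576473663491394
56,0.0432355247618545,0.581103949247519
57,0.0436700490096829,0.585771425854746
58,0.044108940298804,0.590476392033171
59,0.0445522425187126,0.595219148902236
60,0.045,0.6
61,0.0454522575187876,0.604819251302564
62,0.045909060301204,0.609677211243657
63,0.0463704540279083,0.614574190734373
64,0.0468364848386575,0.619510503183071
65,0.0473071993369211,0.624486464515433
66,0.0477826445945412,0.629502393194682
67,0.0482628681564397,0.634558610241967
68,0.0487479180453731,0.639655439256903
69,0.0492378427667345,0.644793206438288
70,0.0497326913134041,0.649972240604975
71,0.0502325131706492,0.655192873216918
72,0.0507373583210719,0.660455438396387
73,0.051247277249608,0.665760272949349
74,0.0517623209485752,0.671107716387027
75,0.0522825409227727,0.676498110947625
76,0.0528079891946315,0.681931801618236
77,0.0533387183094164,0.687409136156917
78,0.0538747813404815,0.692930465114948
79,0.0544162318945763,0.698496141859267
80,0.0549631241172076,0.704106522595086
81,0.0555155126980534,0.709761966388686
82,0.0560734528764321,0.715462835190402
83,0.0566370004468265,0.721209493857781
84,0.0572062117644632,0.72700231017894
85,0.0577811437509484,0.732841654896102
86,0.0583618538999597,0.738727901729321
87,0.0589484002829961,0.744661427400403
88,0.0595408415551847,0.750642611657017
89,0.0601392369611462,0.756671837296998
90,0.0607436463409201,0.762749490192843
91,0.061354130135948,0.768875959316413
92,0.0619707493951181,0.775051636763822
93,0.0625935657808701,0.781276917780536
94,0.0632226415753617,0.787552200786665
95,0.0638580396866966,0.793877887402462
96,0.0644998236552153,0.800254382474031
97,0.0651480576598496,0.806682094099232
98,0.0658028065245401,0.813161433653803
99,0.0664641357247189,0.819692815817688
100,0.0671321113938572,0.826276658601574
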