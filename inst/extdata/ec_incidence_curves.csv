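"gene","age","rate"
"MLH1",40,1.48958167170618
"MLH1",41,1.4372705479748
"MLH1",42,1.38567586525252
"MLH1",43,1.33486536550162
"MLH1",44,1.28490272248252
"MLH1",45,1.23584722906235
"MLH1",46,1.18775353598982
"MLH1",47,1.1406714438286
"MLH1",48,1.09464574871316
"MLH1",49,1.04971614160049
"MLH1",50,1.00591715976331
"MLH1",51,0.963278188428487
"MLH1",52,0.921823509724557
"MLH1",53,0.881572395478244
"MLH1",54,0.842539239898423
"MLH1",55,0.804733727810651
"MLH1",56,0.772186031696658
"MLH1",57,0.740593490175624
"MLH1",58,0.709956570943065
"MLH1",59,0.680273240998343
"MLH1",60,0.651539113077575
"MLH1",61,0.623502159488696
"MLH1",62,0.596411875219995
"MLH1",63,0.57025806541552
"MLH1",64,0.545028695387474
"MLH1",65,0.520710059171598
"MLH1",66,0.496375986850549
"MLH1",67,0.472985932454442
"MLH1",68,0.450520945420329
"MLH1",69,0.428960768413734
"MLH1",70,0.408284023668639
"MLH1",71,0.386223739613587
"MLH1",72,0.365197452740042
"MLH1",73,0.345173323439638
"MLH1",74,0.326118689110274
"MLH1",75,0.308000308000308
"MLH1",76,0.29091127815576
"MLH1",77,0.274676102833261
"MLH1",78,0.259262255208868
"MLH1",79,0.244637338823457
"MLH1",80,0.230769230769231
"MLH1",81,0.217626207531037
"MLH1",82,0.205177054420254
"MLH1",83,0.193391159613544
"MLH1",84,0.182238593855557
"MLH1",85,0.171690176907727
"MSH2",40,1.15262560836505
"MSH2",41,1.15518541941034
"MSH2",42,1.1574121005854
"MSH2",43,1.15929775344327
"MSH2",44,1.16083598916857
"MSH2",45,1.16202193918056
"MSH2",46,1.16285225043484
"MSH2",47,1.16332506603407
"MSH2",48,1.16343999199725
"MSH2",49,1.16319805124325
"MSH2",50,1.16260162601626
"MSH2",51,1.16165439011305
"MSH2",52,1.16036123236649
"MSH2",53,1.15872817289422
"MSH2",54,1.15676227363962
"MSH2",55,1.15447154471545
"MSH2",56,1.15601992232545
"MSH2",57,1.15731277169691
"MSH2",58,1.15835365236636
"MSH2",59,1.15914664019089
"MSH2",60,1.1596962816475
"MSH2",61,1.16559239693972
"MSH2",62,1.17126761576461
"MSH2",63,1.17672413275685
"MSH2",64,1.18196455609911
"MSH2",65,1.1869918699187
"MSH2",66,1.19790581329355
"MSH2",67,1.20864641626518
"MSH2",68,1.21921441397885
"MSH2",69,1.22961092140386
"MSH2",70,1.23983739837398
"MSH2",71,1.25345988299653
"MSH2",72,1.26690425141721
"MSH2",73,1.28017186924345
"MSH2",74,1.29326449535464
"MSH2",75,1.3061842330135
"MSH2",76,1.32084427778283
"MSH2",77,1.3353592586783
"MSH2",78,1.3497305675962
"MSH2",79,1.36395981182626
"MSH2",80,1.3780487804878
"MSH2",81,1.39199941340246
"MSH2",82,1.40581377240913
"MSH2",83,1.41949401509537
"MSH2",84,1.43304237089291
"MSH2",85,1.44646111946336
"MSH6",40,0.856034107733501
"MSH6",41,0.869970632455601
"MSH6",42,0.883775126999962
"MSH6",43,0.897429261088946
"MSH6",44,0.910915380314094
"MSH6",45,0.924216598384503
"MSH6",46,0.93731687947497
"MSH6",47,0.950201109922862
"MSH6",48,0.962855158746307
"MSH6",49,0.975265926680546
"MSH6",50,0.987421383647799
"MSH6",51,0.999310594782981
"MSH6",52,1.01092373532812
"MSH6",53,1.02225209487829
"MSH6",54,1.03328807160861
"MSH6",55,1.0440251572327
"MSH6",56,1.05140471251443
"MSH6",57,1.05855762560415
"MSH6",58,1.06548264472451
"MSH6",59,1.07217908113938
"MSH6",60,1.07864678095286
"MSH6",61,1.0826418247469
"MSH6",62,1.08641518937426
"MSH6",63,1.0899697765704
"MSH6",64,1.09330886219023
"MSH6",65,1.09643605870021
"MSH6",66,1.09810768537232
"MSH6",67,1.09956652549871
"MSH6",68,1.10081838184123
"MSH6",69,1.10186926795934
"MSH6",70,1.10272536687631
"MSH6",71,1.10255545778954
"MSH6",72,1.1021517714175
"MSH6",73,1.10152369554912
"MSH6",74,1.10068066839382
"MSH6",75,1.0996321268858
"MSH6",76,1.09767956723835
"MSH6",77,1.09553579201938
"MSH6",78,1.09321019402364
"MSH6",79,1.09071201429416
"MSH6",80,1.08805031446541
"MSH6",81,1.08523395329398
"MSH6",82,1.0822715670804
"MSH6",83,1.07917155367837
"MSH6",84,1.07594205978674
"MSH6",85,1.07259097122301
"PMS2",40,0.522097485509022
"PMS2",41,0.536571041999924
"PMS2",42,0.551265430086427
"PMS2",43,0.566173595775498
"PMS2",44,0.581288427362619
"PMS2",45,0.596602813154037
"PMS2",46,0.612109697233239
"PMS2",47,0.627802132549818
"PMS2",48,0.64367333068671
"PMS2",49,0.659716707750517
"PMS2",50,0.675925925925926
"PMS2",51,0.692294930336051
"PMS2",52,0.708817980952621
"PMS2",53,0.725489679400497
"PMS2",54,0.742304990597345
"PMS2",55,0.759259259259259
"PMS2",56,0.774070480387206
"PMS2",57,0.788970101015748
"PMS2",58,0.803954810138014
"PMS2",59,0.819021547044785
"PMS2",60,0.834167500834168
"PMS2",61,0.846965324027478
"PMS2",62,0.859764021094482
"PMS2",63,0.872561730208444
"PMS2",64,0.885356874207387
"PMS2",65,0.898148148148148
"PMS2",66,0.903983909531907
"PMS2",67,0.909677095843355
"PMS2",68,0.915230057841659
"PMS2",69,0.92064539496412
"PMS2",70,0.925925925925926
"PMS2",71,0.930167624282853
"PMS2",72,0.934229534001402
"PMS2",73,0.938116904887794
"PMS2",74,0.941835156104367
"PMS2",75,0.945389834278723
"PMS2",76,0.947362482263054
"PMS2",77,0.949173964750693
"PMS2",78,0.950830524923715
"PMS2",79,0.952338381585766
"PMS2",80,0.953703703703704
"PMS2",81,0.954932588046468
"PMS2",82,0.956031039749812
"PMS2",83,0.957004955622834
"PMS2",84,0.957860110004446
"PMS2",85,0.958602142974357
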