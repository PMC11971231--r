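# source=synthetic placeholder (seed 20240601); not a track-structure result
electron_energy_keV,diameter_nm,yD_keV_per_um
0.10000000000000002,10,64.67619899396858330
0.14075166731218733,10,66.42201300637383099
0.19811031851160654,10,54.81304564442408633
0.27884357642257107,10,50.61075747282001203
0.39247698300770195,10,45.13045940413581292
0.55241789739991043,10,38.71810342798496407
0.77753740112130221,10,39.05250206597396101
1.09439685605408221,10,33.39541418491459268
1.54038182190827944,10,26.85968692133562996
2.16811309730975088,10,20.21094323717566255
3.05165533367737973,10,16.59114377247127692
4.29525576277220456,10,12.33153428235432081
6.04564410142468756,10,9.33615913470990577
8.50934487251614868,10,7.08635075929824065
11.97704478541059459,10,5.24435675602787477
16.85789023019280464,10,4.22403590573357501
23.72776157265469621,10,3.06150533604393260
33.39722002937195100,10,2.37067803192413074
47.00714402726081431,10,2.01662984752114882
66.16333897421087329,10,1.49761816622547173
93.12600275561599972,10,1.05828139275037314
131.07640157972298312,10,0.95292713735858725
184.49222067627823662,10,0.84071164386845831
259.67587666314148009,10,0.70333543267802601
365.49812601091127817,10,0.58680748660847670
514.44470635515676804,10,0.54005905614124960
724.08950159416883707,10,0.49938490771462496
1019.16804632629941807,10,0.52609017437427597
1434.49601791731129197,10,0.51324757804153986
2019.07706274555175696,10,0.46323865612105852
2841.88463013230102661,10,0.49421268152049552
3999.99999999999954525,10,0.50514138076785686
0.10000000000000002,100,45.02511189849732176
0.14075166731218733,100,41.16570308518925714
0.19811031851160654,100,40.77471152179403191
0.27884357642257107,100,41.67167877551608512
0.39247698300770195,100,32.12514389990158037
0.55241789739991043,100,33.88504212964935647
0.77753740112130221,100,25.55968336869187496
1.09439685605408221,100,24.57866452593865603
1.54038182190827944,100,17.24387940689299725
2.16811309730975088,100,15.94351569076656716
3.05165533367737973,100,11.93316818439487825
4.29525576277220456,100,8.95984118325770140
6.04564410142468756,100,6.15934570584528451
8.50934487251614868,100,5.03382200853174133
11.97704478541059459,100,3.67183151171982392
16.85789023019280464,100,2.76376220154690255
23.72776157265469621,100,2.33164368497657515
33.39722002937195100,100,1.89594571633984188
47.00714402726081431,100,1.33963764704046806
66.16333897421087329,100,1.11288516730757592
93.12600275561599972,100,0.84617856463487273
131.07640157972298312,100,0.72165977884993482
184.49222067627823662,100,0.64511006709995222
259.67587666314148009,100,0.51982979629927650
365.49812601091127817,100,0.45112564257051718
514.44470635515676804,100,0.44124158233433275
724.08950159416883707,100,0.41547721822319433
1019.16804632629941807,100,0.34755678699718112
1434.49601791731129197,100,0.34445727361655082
2019.07706274555175696,100,0.37494619612713237
2841.88463013230102661,100,0.38235588542275989
3999.99999999999954525,100,0.40266697567282694
0.10000000000000002,1000,40.09684373471488072
0.14075166731218733,1000,38.17658253279647340
0.19811031851160654,1000,35.37476889923159717
0.27884357642257107,1000,31.29163442890760649
0.39247698300770195,1000,29.36083109494229149
0.55241789739991043,1000,27.60339632059691439
0.77753740112130221,1000,23.33912219982623526
1.09439685605408221,1000,19.89131676289085604
1.54038182190827944,1000,16.31054318332503428
2.16811309730975088,1000,11.66820967779690399
3.05165533367737973,1000,9.02586591084715195
4.29525576277220456,1000,7.75381504992139092
6.04564410142468756,1000,5.99184928222305135
8.50934487251614868,1000,4.53937724363409956
11.97704478541059459,1000,3.01637257816287274
16.85789023019280464,1000,2.38807141468643236
23.72776157265469621,1000,1.96378785485941609
33.39722002937195100,1000,1.53254122925069569
47.00714402726081431,1000,1.12015708175853979
66.16333897421087329,1000,0.91784003932194635
93.12600275561599972,1000,0.69230793423331261
131.07640157972298312,1000,0.59130762072643439
184.49222067627823662,1000,0.54804715575591745
259.67587666314148009,1000,0.46000504166715134
365.49812601091127817,1000,0.35783902321691646
514.44470635515676804,1000,0.35334658367130894
724.08950159416883707,1000,0.34323608388386168
1019.16804632629941807,1000,0.31197647975575171
1434.49601791731129197,1000,0.31046027126650044
2019.07706274555175696,1000,0.30378443378240017
2841.88463013230102661,1000,0.31315240874695677
3999.99999999999954525,1000,0.34391223963952949
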