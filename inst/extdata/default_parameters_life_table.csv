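"age","qx"
0,0.000516366636836629
1,0.000518082842655976
2,0.000519977644241276
3,0.000522069626643584
4,0.000524379308827427
5,0.000526929344889848
6,0.000529744746212035
7,0.000532853126720023
8,0.000536284973656542
9,0.000540073946517339
10,0.000544257207078847
11,0.000548875783750069
12,0.000553974973814597
13,0.000559604787501833
14,0.000565820438232389
15,0.000572682883834497
16,0.000580259424025842
17,0.00058862436000473
18,0.000597859722596183
19,0.000608056076071506
20,0.000619313405492261
21,0.000631742096243393
22,0.000645464015316399
23,0.000660613704889346
24,0.00067733969984074
25,0.00069580598203467
26,0.000716193585534319
27,0.000738702368362598
28,0.000763552968030434
29,0.000790988959821992
30,0.000821279238775841
31,0.000854720648439944
32,0.000891640881839795
33,0.000932401682691597
34,0.000977402377745795
35,0.00102708377428129
36,0.0010819324602136
37,0.00114248554806606
38,0.00120933590819705
39,0.00128313794123236
40,0.00136461394463505
41,0.00145456113380404
42,0.0015538593840656
43,0.00166347976644432
44,0.0017844939572188
45,0.00191808460902987
46,0.00206555677974829
47,0.002228350524484
48,0.00240805476606143
49,0.00260642257004229
50,0.00282538796198395
51,0.00306708443710679
52,0.00333386532593205
53,0.00362832619374365
54,0.00395332946692695
55,0.00431203149529324
56,0.00470791227637035
57,0.00514480808520645
58,0.00562694727136182
59,0.00615898950322735
60,0.00674606875833361
61,0.00739384037649626
62,0.00810853250999499
63,0.0088970023208329
64,0.00976679728864438
65,0.0107262220029498
66,0.0117844108188657
67,0.0129514067544161
68,0.0142382469981985
69,0.0156570553758262
70,0.0172211420891989
71,0.0189451109905067
72,0.0208449745784007
73,0.0229382768015133
74,0.0252442236179498
75,0.0277838210807495
76,0.0305800204894625
77,0.0336578698561886
78,0.0370446705682159
79,0.0407701376744377
80,0.0448665616627125
81,0.0493689689119966
82,0.0543152771762253
83,0.0597464414648372
84,0.0657065845047115
85,0.0722431045772491
86,0.0794067519007751
87,0.0872516628541868
88,0.0958353392010146
89,0.10521855707243
90,0.115465187817897
91,0.126641909970925
92,0.138817788575094
93,0.152063695086679
94,0.166451538187475
95,0.18205327335244
96,0.198939657262967
97,0.217178712592924
98,0.236833869909444
99,0.257961757160895
100,0.280609614364382
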