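SYNTHETIC_DEMO_001,,Rx = 60 Gy,Dmax = 66 Gy
Dose (Gy),PTV,Lungs,Heart,Esophagus,SpinalCord,BrachialPlexus
0,350,2689.79864562525,514.889361059707,39.7322859630286,50,30
1,350,2654.79980386335,503.334630254049,39.6734971538736,48.8888888888889,29.4545454545455
2,350,2616.41530104276,490.544685716186,39.6019279253238,47.7777777777778,28.9090909090909
3,350,2574.44680529854,476.477776919432,39.514862600629,46.6666666666667,28.3636363636364
4,350,2528.71359334364,461.114870099411,39.4090387322691,45.5555555555556,27.8181818181818
5,350,2479.06005894299,444.464939509292,39.2805516015163,44.4444444444444,27.2727272727273
6,350,2425.3639543156,426.569701575002,39.1247491625548,43.3333333333333,26.7272727272727
7,350,2367.54511956676,407.507219505236,38.9361202569254,42.2222222222222,26.1818181818182
8,350,2305.57435049705,387.393783735477,38.708181412062,41.1111111111111,25.6363636363636
9,350,2239.48195001299,366.383540369533,38.4333710881294,40,25.0909090909091
10,350,2169.36541537317,344.665510086995,38.1029650728973,38.8888888888889,24.5454545454545
11,350,2095.39564800762,322.45790720625,37.7070329640453,37.7777777777778,24
12,350,2017.82105120328,300,37.2344631862661,36.6666666666667,23.4545454545455
13,350,1936.96891867739,277.54209279375,36.6730921402431,35.5555555555556,22.9090909090909
14,350,1853.24362430775,255.334489913005,36.0099804352126,34.4444444444444,22.3636363636364
15,350,1767.121302176,233.616459630467,35.2318831191153,33.3333333333333,21.8181818181818
16,350,1679.14094780158,212.606216264523,34.3259574039805,32.2222222222222,21.2727272727273
17,350,1589.89215529372,192.492780494764,33.280735405357,31.1111111111111,20.7272727272727
18,350,1500,173.430298424998,32.0873555423433,30,20.1818181818182
19,350,1410.10784470628,155.535060490708,30.7409913399607,28.8888888888889,19.6363636363636
20,350,1320.85905219842,138.885129900589,29.2423431452002,27.7777777777778,19.0909090909091
21,350,1232.878697824,123.522223080568,27.5989792451045,26.6666666666667,18.5454545454545
22,350,1146.75637569225,109.455314283814,25.8262522490318,25.5555555555556,18
23,350,1063.03108132261,96.6653697459511,23.9475064044981,24.4444444444444,17.4545454545455
24,350,982.178948796719,85.1106389402927,21.9933598924991,23.3333333333333,16.9090909090909
25,350,904.604351992384,74.7320149124499,20,22.2222222222222,16.3636363636364
26,350,830.63458462683,65.4580927173677,18.0066401075009,21.1111111111111,15.8181818181818
27,350,760.518049987013,57.2096789394657,16.0524935955019,20,15.2727272727273
28,350,694.425649502947,49.9036178963534,14.1737477509682,18.8888888888889,14.7272727272727
29,350,632.454880433241,43.4558912169106,12.4010207548955,17.7777777777778,14.1818181818182
30,350,574.636045684403,37.7840136341979,10.7576568547998,16.6666666666667,13.6363636363636
31,350,520.939941057015,32.8087903295645,9.25900866003929,15.5555555555556,13.0909090909091
32,350,471.286406656358,28.4555239065401,7.91264445765673,14.4444444444444,12.5454545454545
33,350,425.553194701463,24.654766920279,6.71926459464302,13.3333333333333,12
34,350,383.584698957244,21.3427135635817,5.67404259601951,12.2222222222222,11.4545454545455
35,350,345.200196136649,18.4613156142888,4.7681168808847,11.1111111111111,10.9090909090909
36,350,310.201354374749,15.9581961461195,3.99001956478741,10,10.3636363636364
37,350,278.378859351471,13.7864219460154,3.32690785975689,8.88888888888889,9.81818181818182
38,350,249.518089481767,11.9041834404465,2.76553681373387,7.77777777777778,9.27272727272727
39,350,223.403835498084,10.2744199894366,2.29296703595475,6.66666666666667,8.72727272727273
40,350,199.824106725272,8.86441901596383,1.89703492710267,5.55555555555556,8.18181818181818
41,350,178.573097929505,7.64540967846696,1.56662891187057,4.44444444444445,7.63636363636364
42,350,159.453409194191,6.59216557835591,1.29181858793802,3.33333333333333,7.09090909090909
43,350,142.2776195327,5.68262614916767,1.06387974307463,2.22222222222222,6.54545454545454
44,350,126.869315526101,4.89754269189594,0.875250837445219,1.11111111111111,6
45,350,113.063671525818,4.2201522929971,0.719448398483662,0,5.45454545454545
46,350,100.707669844448,3.63588089495047,0.590961267730922,0,4.90909090909091
47,350,89.6600394109087,3.13207541613504,0.485137399370969,0,4.36363636363637
48,350,79.7909807305976,2.69776389656471,0.398072074676173,0,3.81818181818182
49,350,70.9817344663836,2.32344206440262,0.326502846126396,0,3.27272727272727
50,350,63.1240410614048,2.00088438444801,0.267714036971394,0,2.72727272727273
51,350,56.1195298630638,1.72297749342024,0.219451955978016,0,2.18181818181818
52,350,49.8790683236449,1.48357389398086,0.179850926437647,0,1.63636363636364
53,350,44.3220950798192,1.27736382957851,0.147369595977439,0,1.09090909090909
54,350,39.3759550113084,1.09976336549568,0.120736652988337,0,0.545454545454546
55,350,34.9752496644993,0.946816836242317,0.098904926265391,0,0
56,350,31.0612125932753,0.815111970257375,0.0810128155619953,0,0
57,350,27.5811161018643,0.701706159033309,0.0663520432069769,0,0
58,350,24.4877134594797,0.604062492051383,0.0543407980171583,0,0
59,350,21.7387187874943,0.519994326647519,0.0445014413144128,0,0
60,350,19.2963254007559,0.447617300302019,0.0364420477760258,0,0
61,0,17.12676233107,0.385307820351592,0.0298411533534679,0,0
62,0,15.1998880003988,0.33166718215416,0.024435174377376,0,0
63,0,13.4888194828235,0.285490571303002,0.0200080442831826,0,0
64,0,11.9695954469823,0.24574029899163,0.016382686599442,0,0
65,0,10.6208706628395,0.211522702722743,0.0134140052186591,0,0
66,0,9.42363985448828,0.182068218017352,0.0109831262440533,0,0
67,0,8.36098865712684,0.156714191457432,0.00899267080933181,0,0
68,0,7.41786946990432,0.134890062139977,0.00736287619853696,0,0
69,0,6.58090007012624,0.116104588260762,0.0060284143223903,0,0
70,0,5.83818295525667,0.0999348388664016,0.00493578303944927,0,0
71,0,5.17914349721146,0.0860167085407565,0.00404116775631091,0,0
72,0,4.59438512100986,0.074036745591739,0.00330868891406666,0,0
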