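energy_kev	photoelectric	incoherent	coherent
1	1100.31	0.0266566	2.16109
1.08061	895.63	0.0286789	2.13453
1.16771	728.445	0.0308457	2.10604
1.26183	591.989	0.0331691	2.07547
1.36354	480.697	0.0357383	2.04164
1.47345	389.667	0.0385697	2.00432
1.5596	334.395	0.0407832	1.97511
1.5596	4068.54	0.0408237	1.97458
1.59222	3968.03	0.04165	1.96367
1.72056	3347.26	0.0449759	1.91973
1.85924	2736.01	0.0485491	1.87246
2.00911	2235.16	0.0523733	1.8218
2.17105	1830	0.0564528	1.76767
2.34605	1495.85	0.0607908	1.71002
2.53516	1220.23	0.0653668	1.64909
2.7395	993.38	0.0698498	1.58924
2.96032	807.058	0.0742452	1.5304
3.19894	653.941	0.078647	1.47129
3.45679	528.533	0.0831066	1.41122
3.73542	426.613	0.0876506	1.3498
4.03652	343.89	0.0922124	1.2879
4.36188	276.84	0.0967685	1.2258
4.71347	222.567	0.101353	1.16301
5.0934	178.696	0.105979	1.09933
5.50396	143.282	0.110625	1.03501
5.94761	114.732	0.115291	0.970003
6.42701	91.7474	0.119965	0.904421
6.94506	73.2559	0.124587	0.839054
7.50487	58.4058	0.129152	0.773911
8.1098	46.5181	0.133578	0.710083
8.7635	37.0117	0.137836	0.647915
9.46988	29.3714	0.141853	0.588383
10.2332	23.2812	0.145605	0.531788
11.058	18.4401	0.149037	0.47888
11.9494	14.5948	0.152139	0.429754
12.9126	11.5427	0.154899	0.384586
13.9534	9.12202	0.157314	0.343369
15.0781	7.20355	0.159397	0.305933
16.2935	5.68426	0.161163	0.27204
17.6068	4.482	0.162628	0.241427
19.026	3.53135	0.16381	0.213826
20.5596	2.78021	0.164726	0.188989
22.2168	2.18718	0.165387	0.166688
24.0076	1.71933	0.165809	0.146719
25.9428	1.35052	0.166	0.128898
28.0339	1.05988	0.165974	0.113036
30.2936	0.831164	0.165741	0.0989496
32.7354	0.651365	0.165312	0.0864676
35.374	0.51012	0.164695	0.0754322
38.2253	0.399236	0.163901	0.065694
41.3065	0.312246	0.162937	0.0571173
44.636	0.244046	0.161811	0.0495806
48.2339	0.190616	0.160531	0.0429747
52.1218	0.148783	0.159102	0.0372003
56.3231	0.116053	0.157533	0.0321664
60.863	0.090463	0.155829	0.0277887
65.7689	0.0704683	0.153996	0.0239887
71.0702	0.0548562	0.152042	0.0206949
76.7989	0.0426743	0.149974	0.0178426
82.9893	0.0331754	0.147796	0.0153745
89.6786	0.0257736	0.145518	0.01324
96.9072	0.0200098	0.143144	0.0113953
104.718	0.0155246	0.140683	0.00980219
113.159	0.0120367	0.138142	0.00842745
122.28	0.00932614	0.135528	0.00724208
132.137	0.00722115	0.132848	0.00622072
142.788	0.00558753	0.13011	0.00534139
154.297	0.00432059	0.127323	0.00458474
166.734	0.00333868	0.124493	0.00393407
180.174	0.0025782	0.12163	0.00337488
194.697	0.00198961	0.118739	0.00289447
210.391	0.00153436	0.11583	0.00248193
227.349	0.00118249	0.112908	0.00212787
245.675	0.000910702	0.109982	0.001824
265.477	0.000700915	0.107057	0.00156332
286.876	0.000539094	0.104139	0.00133972
310	0.000414355	0.101234	0.00114804
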