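energy_kev	photoelectric	incoherent	coherent
1	2625	0.0104861	10.3589
1.08061	2261.54	0.0112964	10.3033
1.16771	1945.19	0.0121685	10.2433
1.26183	1670.08	0.0131116	10.1784
1.36354	1430.6	0.0142432	10.1005
1.4093	1339.86	0.0147808	10.0634
1.4093	34621.4	0.0147979	10.0623
1.4533	8067.39	0.0153203	10.0263
1.4533	29277.5	0.0153384	10.025
1.47345	14928	0.0155807	10.0083
1.59222	5306.37	0.0171007	9.90347
1.72056	4355.44	0.018794	9.78655
1.8118	3820.79	0.0200059	9.70279
1.8118	4471.69	0.0200303	9.70111
1.85924	4173.34	0.0206593	9.65761
2.0058	3471.89	0.0226402	9.5205
2.0058	3705.06	0.0226676	9.5186
2.00911	3694.47	0.0226991	9.51641
2.17105	3064.69	0.0249184	9.36258
2.2065	2954.58	0.0253901	9.32986
2.2065	3082.44	0.0254204	9.32776
2.34605	2676.34	0.0273229	9.19566
2.53516	2233.73	0.0299198	9.01506
2.7395	1859.77	0.0327373	8.81877
2.96032	1544.84	0.0357807	8.60632
3.19894	1279.24	0.0390488	8.3777
3.45679	1057.59	0.0425419	8.13274
3.73542	873.136	0.0462605	7.87129
4.03652	719.841	0.050157	7.59652
4.36188	592.605	0.0542124	7.30962
4.71347	487.295	0.0584423	7.00929
5.0934	400.306	0.0628393	6.69588
5.50396	328.537	0.0672723	6.37845
5.94761	269.386	0.0717491	6.05624
6.42701	220.659	0.0762771	5.72853
6.94506	180.571	0.0807495	5.40272
7.50487	147.645	0.0851909	5.07684
8.1098	120.618	0.0895488	4.75443
8.3579	111.622	0.0911884	4.63237
8.3579	317.949	0.0912435	4.62825
8.7635	273.616	0.0938141	4.43594
9.2643	236.032	0.096767	4.21346
9.2643	328.751	0.0968199	4.20946
9.46988	308.731	0.097949	4.12389
9.7513	284.203	0.0994488	4.00978
9.7513	327.773	0.0995006	4.00583
10.2332	290.327	0.101942	3.81889
11.058	237.742	0.105747	3.52406
11.9494	194.457	0.109347	3.24055
12.9126	158.816	0.112712	2.97036
13.9534	129.563	0.115816	2.7152
15.0781	105.591	0.118646	2.47594
16.2935	85.9693	0.121197	2.25285
17.6068	69.9123	0.123472	2.04562
19.026	56.7931	0.125479	1.85348
20.5596	46.0856	0.127231	1.67536
22.2168	37.3678	0.128741	1.51008
24.0076	30.2773	0.130022	1.35665
25.9428	24.5142	0.13108	1.21434
28.0339	19.825	0.131921	1.08265
30.2936	16.0201	0.132548	0.961303
32.7354	12.939	0.132962	0.850115
35.374	10.4452	0.133164	0.749038
38.2253	8.42521	0.133156	0.657894
41.3065	6.79081	0.132943	0.576341
44.636	5.46623	0.132533	0.503869
48.2339	4.39778	0.131934	0.439819
52.1218	3.53735	0.131156	0.383428
56.3231	2.84456	0.130211	0.3339
57.4855	2.68945	0.129942	0.322182
57.4855	14.5306	0.129928	0.321605
60.863	12.5734	0.129109	0.290462
65.7689	10.2579	0.127861	0.252395
71.0702	8.36034	0.126476	0.219063
76.7989	6.80705	0.124963	0.189903
82.9893	5.532	0.123332	0.164426
89.6786	4.48845	0.12159	0.142198
96.9072	3.63913	0.119746	0.122837
104.718	2.94838	0.117809	0.106001
113.159	2.38699	0.115786	0.0913864
122.28	1.92326	0.113686	0.0787192
132.137	1.54837	0.111517	0.0677559
142.788	1.24698	0.109287	0.0582806
154.297	1.00461	0.107004	0.0501006
166.734	0.809633	0.104677	0.0430464
180.174	0.65272	0.102312	0.0369686
194.697	0.526401	0.099918	0.0317366
210.391	0.424675	0.0975016	0.0272359
227.349	0.342728	0.0950698	0.0233665
245.675	0.276691	0.092629	0.0200418
265.477	0.223457	0.0901855	0.0171863
286.876	0.18053	0.0877447	0.014735
310	0.145903	0.0853118	0.0126312
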