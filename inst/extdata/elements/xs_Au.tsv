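energy_kev	photoelectric	incoherent	coherent
1	4444.44	0.00818259	12.0443
1.08061	3832.19	0.00881433	11.9939
1.16771	3297.29	0.00949468	11.9395
1.26183	2831.49	0.0102344	11.8804
1.36354	2424.88	0.0112026	11.803
1.47345	2067.66	0.0124216	11.7054
1.59222	1758.49	0.0138543	11.5906
1.72056	1491.92	0.015484	11.46
1.85924	1264.01	0.0173053	11.3138
2.00911	1069.46	0.0193187	11.152
2.17105	903.513	0.0215279	10.9742
2.2057	873.695	0.0219884	10.9371
2.2057	11895.6	0.0220188	10.9347
2.2911	2975.09	0.0231635	10.8424
2.2911	10033.1	0.0231951	10.8399
2.34605	4624.3	0.0239378	10.78
2.53516	2638.04	0.0265534	10.5689
2.7395	2172.48	0.0293773	10.3405
2.743	2168.2	0.0294066	10.3381
2.743	2510.96	0.0294444	10.3351
2.96032	2090.34	0.0324142	10.0944
3.1478	1798.55	0.0349528	9.88831
3.1478	1912.19	0.0349956	9.88483
3.19894	1839.22	0.035669	9.8301
3.4249	1557.59	0.0386948	9.58384
3.4249	1621.54	0.0387407	9.5801
3.45679	1588.05	0.0391451	9.54715
3.73542	1319.15	0.0428445	9.24524
4.03652	1094.02	0.0466892	8.93053
4.36188	905.703	0.050649	8.60534
4.71347	748.221	0.054753	8.26708
5.0934	617.181	0.0590034	7.91537
5.50396	508.542	0.0632876	7.55924
5.94761	418.455	0.0676158	7.19764
6.42701	343.955	0.0719962	6.82964
6.94506	282.383	0.0763277	6.46338
7.50487	231.62	0.0806357	6.09653
8.1098	189.832	0.0848713	5.7329
8.7635	155.459	0.0890277	5.37281
9.46988	127.123	0.0930823	5.0179
10.2332	103.86	0.0970303	4.66831
11.058	84.8013	0.100847	4.32587
11.9187	69.7728	0.104378	4.00442
11.9187	182.602	0.104424	4.00016
11.9494	181.562	0.10452	3.99135
12.9126	146.832	0.108026	3.66653
13.7336	124.278	0.110654	3.41858
13.7336	173.407	0.110696	3.41459
13.9534	166.332	0.111336	3.35352
14.3528	154.293	0.112467	3.24493
14.3528	178.022	0.112507	3.24105
15.0781	157.284	0.114426	3.05434
16.2935	128.858	0.117273	2.77073
17.6068	105.459	0.119858	2.50409
19.026	86.2075	0.122172	2.25529
20.5596	70.3975	0.124208	2.02464
22.2168	57.4274	0.125968	1.81198
24.0076	46.7977	0.127456	1.61681
25.9428	38.0952	0.128678	1.4386
28.0339	30.9651	0.129642	1.27645
30.2936	25.134	0.13036	1.12939
32.7354	20.3882	0.13084	0.996542
35.374	16.5297	0.131091	0.877092
38.2253	13.3943	0.131122	0.77012
41.3065	10.8476	0.130945	0.674671
44.636	8.78025	0.13057	0.589802
48.2339	7.10277	0.130007	0.5146
52.1218	5.74215	0.129266	0.448187
56.3231	4.63843	0.128358	0.389731
60.863	3.74471	0.127292	0.338436
65.7689	3.02046	0.126078	0.293538
71.0702	2.43552	0.124725	0.25432
76.7989	1.9635	0.123244	0.220116
80.7249	1.71166	0.122238	0.200673
80.7249	8.383	0.122217	0.200296
82.9893	7.82211	0.121643	0.190323
89.6786	6.41125	0.119931	0.164404
96.9072	5.24154	0.118117	0.141881
104.718	4.27883	0.11621	0.122336
113.159	3.48932	0.114217	0.105397
122.28	2.83839	0.112147	0.0907354
132.137	2.30774	0.110009	0.0780609
142.788	1.87579	0.107811	0.0671171
154.297	1.52427	0.10556	0.0576769
166.734	1.23828	0.103264	0.0495414
180.174	1.00567	0.100932	0.0425361
194.697	0.816519	0.0985709	0.0365085
210.391	0.662753	0.0961874	0.0313254
227.349	0.537786	0.0937886	0.026871
245.675	0.436254	0.091381	0.0230446
265.477	0.353785	0.0889705	0.019759
286.876	0.286819	0.0865628	0.0169392
310	0.232458	0.0841628	0.0145196
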