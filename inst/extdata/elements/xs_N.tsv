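energy_kev	photoelectric	incoherent	coherent
1	3169.34	0.0234769	1.23637
1.08061	2563.92	0.0252617	1.22374
1.16771	2071.25	0.0271765	1.21019
1.26183	1670.92	0.0292475	1.19552
1.36354	1346.09	0.0318901	1.17679
1.47345	1082.89	0.0351487	1.15368
1.59222	869.941	0.0389185	1.12692
1.72056	697.305	0.043145	1.09688
1.85924	558.226	0.0477999	1.06377
2.00911	446.379	0.0528673	1.02767
2.17105	356.537	0.0583354	0.988668
2.34605	284.453	0.0641916	0.946827
2.53516	226.685	0.070404	0.902364
2.7395	180.444	0.0767187	0.857073
2.96032	143.471	0.0831264	0.811007
3.19894	113.847	0.0896747	0.76381
3.45679	90.2353	0.0963737	0.715391
3.73542	71.4524	0.103207	0.665846
4.03652	56.5251	0.109782	0.617993
4.36188	44.6735	0.115959	0.57281
4.71347	35.273	0.121885	0.529238
5.0934	27.824	0.127595	0.487
5.50396	21.9271	0.132797	0.448222
5.94761	17.2633	0.13755	0.412453
6.42701	13.5785	0.141927	0.379158
6.94506	10.67	0.145778	0.34944
7.50487	8.37645	0.149183	0.322694
8.1098	6.56876	0.152109	0.299178
8.7635	5.14732	0.154571	0.278763
9.46988	4.02414	0.156576	0.261421
10.2332	3.14341	0.15814	0.247016
11.058	2.45442	0.159266	0.235545
11.9494	1.91565	0.159964	0.226937
12.9126	1.49452	0.160228	0.22125
13.9534	1.16548	0.160041	0.218633
15.0781	0.908515	0.159373	0.21934
16.2935	0.707911	0.15818	0.223756
17.6068	0.551373	0.156397	0.232429
19.026	0.429272	0.153942	0.246094
20.5596	0.334072	0.150707	0.265703
22.2168	0.259877	0.146562	0.292435
24.0076	0.202077	0.141354	0.327715
25.9428	0.157067	0.134909	0.373226
28.0339	0.121845	0.127053	0.430716
30.2936	0.0944254	0.117643	0.501801
32.7354	0.0731721	0.106541	0.588131
35.374	0.0566995	0.0936874	0.6908
38.2253	0.0439329	0.0816845	0.810022
41.3065	0.034039	0.0721715	0.944874
44.636	0.0263719	0.064186	1.093
48.2339	0.0204307	0.0572049	1.25047
52.1218	0.0158271	0.0509523	1.41187
56.3231	0.0122601	0.0452861	1.57068
60.863	0.00949651	0.0401331	1.71936
65.7689	0.00735548	0.0354525	1.8512
71.0702	0.00569683	0.031217	1.96003
76.7989	0.00441197	0.0274028	2.04155
82.9893	0.0034167	0.0239859	2.09346
89.6786	0.0026458	0.0209404	2.11582
96.9072	0.00204873	0.0182389	2.10953
104.718	0.00158631	0.0158528	2.0765
113.159	0.00122819	0.0137535	2.01921
122.28	0.000950865	0.0119129	1.94046
132.137	0.00073612	0.0119098	1.84338
142.788	0.000569841	0.0145492	1.73145
154.297	0.000441098	0.0187416	1.60858
166.734	0.000341422	0.0237557	1.4789
180.174	0.000264255	0.0290852	1.34656
194.697	0.000204518	0.0343686	1.21562
210.391	0.000158276	0.0393571	1.08959
227.349	0.000122482	0.0438917	0.971254
245.675	9.47782e-05	0.0478905	0.862377
265.477	7.33362e-05	0.0513351	0.763686
286.876	5.6742e-05	0.0542462	0.675115
310	4.39001e-05	0.0566682	0.595993
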