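energy_kev	photoelectric	incoherent	coherent
1	10553.8	0.012499	4.93779
1.08061	8465.38	0.013465	4.90948
1.0961	8177.63	0.0136437	4.90424
1.0961	9087.13	0.0136568	4.90386
1.16771	7960.22	0.0145044	4.879
1.26183	6606.05	0.0156312	4.84594
1.36354	5472.27	0.0170529	4.80419
1.47345	4522.11	0.0187969	4.75294
1.59222	3728.72	0.0208175	4.69352
1.72056	3069.68	0.023094	4.62651
1.85924	2523.07	0.0256193	4.55209
2.00911	2070.53	0.0283939	4.47022
2.17105	1696.52	0.031421	4.38077
2.34605	1387.7	0.0347056	4.28356
2.53516	1133.45	0.0382537	4.17838
2.7395	924.483	0.0420876	4.06453
2.96032	753.015	0.04621	3.94185
3.19894	612.117	0.0506171	3.81043
3.45679	497.037	0.0553049	3.67029
3.73542	403.22	0.060268	3.52153
4.03652	326.596	0.06544	3.36604
4.36188	264.332	0.0707897	3.20468
4.71347	213.794	0.0763273	3.03704
5.0934	172.727	0.0820318	2.86365
5.50396	139.458	0.0877278	2.6897
5.94761	112.53	0.0934165	2.51505
6.42701	90.7478	0.0990907	2.33982
6.94506	73.1379	0.104576	2.16921
7.50487	58.9096	0.109905	2.00214
8.1098	47.4201	0.114975	1.84167
8.7635	38.1475	0.119772	1.68817
8.9789	35.6715	0.121182	1.64268
8.9789	287.401	0.121241	1.64079
9.46988	246.646	0.12424	1.5433
10.2332	201.937	0.128376	1.4071
11.058	164.996	0.132143	1.28068
11.9494	134.476	0.135551	1.16366
12.9126	109.303	0.138599	1.05602
13.9534	88.706	0.141301	0.957357
15.0781	71.8797	0.143676	0.866971
16.2935	58.155	0.145747	0.78407
17.6068	46.9775	0.147539	0.707856
19.026	37.8681	0.149072	0.637603
20.5596	30.4805	0.150362	0.572709
22.2168	24.5037	0.151422	0.512724
24.0076	19.674	0.15226	0.457337
25.9428	15.7765	0.152879	0.406376
28.0339	12.6298	0.153282	0.359699
30.2936	10.0979	0.153472	0.3172
32.7354	8.06571	0.153452	0.278763
35.374	6.43622	0.153224	0.24428
38.2253	5.13086	0.152795	0.213574
41.3065	4.08014	0.152171	0.186404
44.636	3.24121	0.151362	0.162478
48.2339	2.57334	0.150376	0.141478
52.1218	2.04193	0.149224	0.123078
56.3231	1.61934	0.147916	0.10697
60.863	1.28346	0.14646	0.0928769
65.7689	1.01667	0.144866	0.0805518
71.0702	0.804857	0.14314	0.0697824
76.7989	0.636802	0.141292	0.0603829
82.9893	0.503539	0.139329	0.0521911
89.6786	0.397927	0.137257	0.0450627
96.9072	0.314279	0.135086	0.0388696
104.718	0.248066	0.132822	0.0334975
113.159	0.195685	0.130473	0.0288446
122.28	0.154272	0.128047	0.0248203
132.137	0.12155	0.125553	0.0213437
142.788	0.0957102	0.122999	0.0183441
154.297	0.0753182	0.120392	0.0157582
166.734	0.059235	0.117741	0.0135312
180.174	0.0465579	0.115053	0.0116145
194.697	0.0365717	0.112337	0.00996617
210.391	0.0287101	0.109599	0.00854942
227.349	0.0225248	0.106848	0.00733231
245.675	0.0176614	0.10409	0.00628716
265.477	0.0138397	0.101331	0.00538996
286.876	0.0108384	0.0985774	0.00462023
310	0.00848289	0.0958347	0.00395984
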