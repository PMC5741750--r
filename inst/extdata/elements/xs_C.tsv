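energy_kev	photoelectric	incoherent	coherent
1	2072.58	0.0299979	1.01993
1.08061	1669.07	0.0322745	1.00613
1.16771	1341.47	0.0347117	0.991343
1.26183	1075.78	0.0373354	0.975411
1.36354	861.731	0.0405324	0.955985
1.47345	689.488	0.044341	0.932826
1.59222	551.047	0.0486608	0.906535
1.72056	439.903	0.0534374	0.877433
1.85924	350.778	0.0586397	0.845699
2.00911	279.391	0.064247	0.811449
2.17105	222.279	0.0702408	0.774783
2.34605	176.641	0.0765999	0.735818
2.53516	140.213	0.0832713	0.694864
2.7395	111.171	0.0898438	0.654423
2.96032	88.0442	0.096314	0.614506
3.19894	69.6107	0.102775	0.57453
3.45679	54.977	0.109262	0.534271
3.73542	43.3783	0.115771	0.493729
4.03652	34.194	0.121932	0.455186
4.36188	26.9285	0.127621	0.419393
4.71347	21.1866	0.132987	0.385421
5.0934	16.6532	0.138081	0.352945
5.50396	13.0728	0.142698	0.323236
5.94761	10.2493	0.146894	0.295943
6.42701	8.03019	0.150738	0.270616
6.94506	6.2872	0.154181	0.247569
7.50487	4.91915	0.157279	0.226441
8.1098	3.84613	0.160051	0.207096
8.7635	3.0051	0.162527	0.189351
9.46988	2.34231	0.164733	0.173015
10.2332	1.82424	0.166695	0.15792
11.058	1.42028	0.168436	0.143911
11.9494	1.1054	0.169973	0.13086
12.9126	0.860043	0.17132	0.118665
13.9534	0.668923	0.172485	0.107251
15.0781	0.5201	0.173475	0.0965727
16.2935	0.404252	0.174291	0.086603
17.6068	0.314103	0.174932	0.0773337
19.026	0.243975	0.175395	0.0687674
20.5596	0.189442	0.175678	0.0609095
22.2168	0.147048	0.175779	0.0537602
24.0076	0.114103	0.175699	0.0473101
25.9428	0.08851	0.175437	0.041541
28.0339	0.0685095	0.174999	0.0364111
30.2936	0.0529725	0.174392	0.0318661
32.7354	0.0409629	0.173621	0.0278516
35.374	0.031679	0.172692	0.0243143
38.2253	0.0245016	0.171613	0.0212007
41.3065	0.0189521	0.170389	0.018462
44.636	0.0146609	0.169025	0.0160553
48.2339	0.0113424	0.167526	0.0139429
52.1218	0.00877582	0.165896	0.0120917
56.3231	0.00679066	0.16414	0.0104724
60.863	0.00525504	0.162262	0.00905886
65.7689	0.00406706	0.160266	0.00782733
71.0702	0.00314793	0.158158	0.00675633
76.7989	0.00243674	0.155942	0.00582647
82.9893	0.00188639	0.153623	0.00502046
89.6786	0.00146048	0.151208	0.00432264
96.9072	0.00113083	0.148701	0.00371929
104.718	0.000875672	0.14611	0.00319821
113.159	0.000678147	0.143441	0.00274865
122.28	0.000525225	0.140701	0.00236117
132.137	0.000406824	0.137897	0.00202745
142.788	0.000315142	0.135036	0.0017403
154.297	0.000244144	0.132127	0.00149332
166.734	0.000189159	0.129178	0.00128102
180.174	0.00014657	0.126194	0.00109866
194.697	0.00011358	0.123185	0.000942058
210.391	8.80238e-05	0.120158	0.000807655
227.349	6.8224e-05	0.11712	0.000692334
245.675	5.28827e-05	0.114078	0.000593377
265.477	4.09948e-05	0.111039	0.000508503
286.876	3.17822e-05	0.108008	0.000435728
310	2.46422e-05	0.104992	0.000373359
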