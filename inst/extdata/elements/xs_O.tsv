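energy_kev	photoelectric	incoherent	coherent
1	4419.04	0.0193733	1.4468
1.08061	3597.11	0.0208742	1.43467
1.16771	2923.51	0.0224864	1.42163
1.26183	2372.35	0.0242347	1.40748
1.36354	1922.1	0.0265285	1.3889
1.47345	1554.87	0.0294132	1.36552
1.59222	1255.85	0.0327877	1.33815
1.72056	1012.75	0.0366008	1.30719
1.85924	815.429	0.0408274	1.27284
2.00911	655.53	0.0454553	1.23517
2.17105	526.049	0.050477	1.19425
2.34605	421.329	0.0558857	1.1501
2.53516	337.062	0.0616677	1.10282
2.7395	269.333	0.067747	1.05302
2.96032	214.962	0.0741088	1.00079
3.19894	171.2	0.0807497	0.946137
3.45679	136.181	0.0876504	0.889202
3.73542	108.217	0.0947772	0.830233
4.03652	85.9104	0.101807	0.771863
4.36188	68.134	0.108616	0.71509
4.71347	53.982	0.115296	0.659139
5.0934	42.727	0.121845	0.604011
5.50396	33.7848	0.127958	0.552205
5.94761	26.6875	0.133681	0.503344
6.42701	21.0601	0.139063	0.456997
6.94506	16.6027	0.143953	0.414413
7.50487	13.0756	0.148427	0.374954
8.1098	10.2875	0.152457	0.338846
8.7635	8.08584	0.156067	0.305878
9.46988	6.34841	0.159269	0.27593
10.2332	4.978	0.162094	0.248748
11.058	3.89695	0.164559	0.224161
11.9494	3.04913	0.166696	0.201894
12.9126	2.38464	0.168529	0.181725
13.9534	1.86408	0.170083	0.163422
15.0781	1.45646	0.171381	0.146771
16.2935	1.13744	0.172443	0.131586
17.6068	0.887874	0.173284	0.117712
19.026	0.692736	0.173917	0.105023
20.5596	0.54023	0.17435	0.0934218
22.2168	0.421097	0.174591	0.0828326
24.0076	0.32808	0.174644	0.0731975
25.9428	0.255489	0.174513	0.0644763
28.0339	0.198547	0.1742	0.0566239
30.2936	0.154125	0.17371	0.0495945
32.7354	0.11963	0.173046	0.0433385
35.374	0.0928458	0.172213	0.0378059
38.2253	0.0720513	0.171218	0.0329362
41.3065	0.0559085	0.170065	0.0286641
44.636	0.043378	0.168762	0.0249238
48.2339	0.0336525	0.167315	0.0216527
52.1218	0.0261048	0.16573	0.0187937
56.3231	0.0202479	0.164013	0.0162961
60.863	0.0157034	0.162168	0.0141158
65.7689	0.0121777	0.160201	0.0122143
71.0702	0.00944257	0.158118	0.010558
76.7989	0.00732102	0.155924	0.00911702
82.9893	0.00567554	0.153624	0.00786539
89.6786	0.00439945	0.151225	0.0067796
96.9072	0.00340993	0.148733	0.00583905
104.718	0.00264269	0.146153	0.00502534
113.159	0.00204787	0.143494	0.00432223
122.28	0.00158677	0.140762	0.00371541
132.137	0.00122936	0.137965	0.00319214
142.788	0.000952359	0.135111	0.00274141
154.297	0.000737694	0.132206	0.00235339
166.734	0.000571356	0.129259	0.00201961
180.174	0.000442479	0.126279	0.00173265
194.697	0.000342636	0.123272	0.00148612
210.391	0.000265295	0.120246	0.00127441
227.349	0.00020539	0.117208	0.00109264
245.675	0.000158995	0.114167	0.000936639
265.477	0.000123068	0.111127	0.000802776
286.876	9.52488e-05	0.108095	0.000688008
310	7.37106e-05	0.105078	0.000589573
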