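energy_kev	photoelectric	incoherent	coherent
1	548.867	0.0406954	0.547684
1.08061	436.408	0.0436863	0.535595
1.16771	346.594	0.0468698	0.522717
1.26183	274.949	0.0502556	0.509008
1.36354	217.864	0.0538986	0.494242
1.47345	172.434	0.0578076	0.478383
1.59222	136.32	0.0619718	0.461467
1.72056	107.647	0.0663851	0.443517
1.85924	84.9077	0.0710417	0.42455
2.00911	66.895	0.0759346	0.40459
2.17105	52.6273	0.0810533	0.383673
2.34605	41.3527	0.0863826	0.361854
2.53516	32.4654	0.0918614	0.339376
2.7395	25.4659	0.0968808	0.318714
2.96032	19.9582	0.101459	0.299795
3.19894	15.597	0.105769	0.281904
3.45679	12.1772	0.109906	0.264655
3.73542	9.50256	0.113918	0.247841
4.03652	7.41106	0.11765	0.232102
4.36188	5.77691	0.121049	0.217647
4.71347	4.50096	0.124202	0.204114
5.0934	3.50516	0.12716	0.191294
5.50396	2.72838	0.129939	0.179105
5.94761	2.12273	0.132564	0.167448
6.42701	1.65074	0.135054	0.15623
6.94506	1.28309	0.137432	0.145351
7.50487	0.996846	0.139705	0.134769
8.1098	0.774093	0.141874	0.124475
8.7635	0.600831	0.14394	0.114454
9.46988	0.465553	0.145891	0.104749
10.2332	0.360526	0.14772	0.095379
11.058	0.279125	0.149407	0.0864204
11.9494	0.21605	0.15094	0.077913
12.9126	0.167187	0.152305	0.0699126
13.9534	0.129344	0.15349	0.062467
15.0781	0.100042	0.154485	0.0556019
16.2935	0.0773598	0.155289	0.0493251
17.6068	0.0598055	0.155902	0.0436279
19.026	0.0462233	0.156326	0.0384881
20.5596	0.0357171	0.156568	0.0338737
22.2168	0.0275921	0.156635	0.0297477
24.0076	0.0213102	0.156532	0.0260716
25.9428	0.0164546	0.156268	0.0228084
28.0339	0.0126881	0.155848	0.01992
30.2936	0.00977872	0.155279	0.0173692
32.7354	0.00753815	0.154566	0.0151221
35.374	0.00581227	0.153717	0.013147
38.2253	0.00448254	0.152735	0.011414
41.3065	0.0034578	0.151625	0.00989607
44.636	0.00266792	0.150392	0.00856894
48.2339	0.00205894	0.149039	0.00741067
52.1218	0.00158932	0.147572	0.00640164
56.3231	0.00122709	0.145994	0.00552419
60.863	0.000947635	0.144308	0.00476248
65.7689	0.000731983	0.142519	0.0041023
71.0702	0.000565534	0.140632	0.00353096
76.7989	0.000437032	0.138649	0.00303716
82.9893	0.000337805	0.136577	0.0026109
89.6786	0.000261165	0.134421	0.0022433
96.9072	0.000201958	0.132184	0.0019266
104.718	0.000156208	0.129873	0.00165395
113.159	0.00012085	0.127494	0.00141941
122.28	9.35152e-05	0.125053	0.00121777
132.137	7.23797e-05	0.122556	0.00104451
142.788	5.60335e-05	0.12001	0.000895709
154.297	4.33887e-05	0.117421	0.000767953
166.734	3.36048e-05	0.114796	0.000658303
180.174	2.60329e-05	0.112142	0.000564245
194.697	2.01717e-05	0.109466	0.000483559
210.391	1.56335e-05	0.106774	0.000414367
227.349	1.21191e-05	0.104073	0.000355068
245.675	9.39677e-06	0.101368	0.000304214
265.477	7.28759e-06	0.0986658	0.000260632
286.876	5.6531e-06	0.0959716	0.000223259
310	4.38617e-06	0.0932901	0.000191269
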