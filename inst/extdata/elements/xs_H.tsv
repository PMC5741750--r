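energy_kev	photoelectric	incoherent	coherent
1	0	0.0583896	0.338792
1.08061	0	0.062831	0.334305
1.16771	0	0.0675867	0.329496
1.26183	0	0.0727173	0.324303
1.36354	0	0.0792061	0.317733
1.47345	0	0.087143	0.30969
1.59222	0	0.0962624	0.300442
1.72056	0	0.106417	0.290133
1.85924	0	0.11752	0.278849
2.00911	0	0.129508	0.266647
2.17105	0	0.142328	0.253581
2.34605	0	0.155916	0.239709
2.53516	0	0.170165	0.225136
2.7395	0	0.184546	0.210395
2.96032	0	0.199003	0.19554
3.19894	0	0.213576	0.180526
3.45679	0	0.228217	0.165395
3.73542	0	0.242813	0.15026
4.03652	0	0.256654	0.135846
4.36188	0	0.269507	0.122388
4.71347	0	0.281576	0.109676
5.0934	0	0.292872	0.0976936
5.50396	0	0.303042	0.0868069
5.94761	0	0.312187	0.0769093
6.42701	0	0.320406	0.0678954
6.94506	0	0.327634	0.059832
7.50487	0	0.333983	0.0526018
8.1098	0	0.339497	0.0461564
8.7635	0	0.344243	0.0404237
9.46988	0	0.348281	0.0353382
10.2332	0	0.35167	0.030836
11.058	0	0.35446	0.0268608
11.9494	0	0.356699	0.0233586
12.9126	0	0.358431	0.0202809
13.9534	0	0.359693	0.0175827
15.0781	0	0.360522	0.0152225
16.2935	0	0.360949	0.0131626
17.6068	0	0.361002	0.0113683
19.026	0	0.360707	0.00980829
20.5596	0	0.360086	0.00845442
22.2168	0	0.359158	0.00728135
24.0076	0	0.357939	0.0062664
25.9428	0	0.356444	0.0053894
28.0339	0	0.354685	0.00463249
30.2936	0	0.352671	0.00397988
32.7354	0	0.350412	0.00341771
35.374	0	0.347914	0.00293385
38.2253	0	0.345185	0.00251765
41.3065	0	0.342228	0.00215988
44.636	0	0.33905	0.00185249
48.2339	0	0.335655	0.00158851
52.1218	0	0.332046	0.0013619
56.3231	0	0.328229	0.00116743
60.863	0	0.324208	0.0010006
65.7689	0	0.319988	0.000857507
71.0702	0	0.315576	0.000734806
76.7989	0	0.310978	0.000629599
82.9893	0	0.306201	0.000539436
89.6786	0	0.301253	0.000462146
96.9072	0	0.296145	0.000395909
104.718	0	0.290886	0.000339147
113.159	0	0.285487	0.000290509
122.28	0	0.27996	0.000248845
132.137	0	0.274318	0.000213143
142.788	0	0.268574	0.000182568
154.297	0	0.262742	0.000156369
166.734	0	0.256836	0.000133923
180.174	0	0.25087	0.000114699
194.697	0	0.24486	9.82343e-05
210.391	0	0.238818	8.41385e-05
227.349	0	0.232759	7.20672e-05
245.675	0	0.226695	6.17205e-05
265.477	0	0.22064	5.28557e-05
286.876	0	0.214604	4.52688e-05
310	0	0.208599	3.87745e-05
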