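energy_kev	photoelectric	incoherent	coherent
1	3514.5	0.00955509	11.2227
1.08061	3012.66	0.0102902	11.1677
1.16771	2578.19	0.0110816	11.1085
1.26183	2204.35	0.0119391	11.0443
1.36354	1882.68	0.0130038	10.9645
1.47345	1605.94	0.0142951	10.8677
1.59222	1367.96	0.0157835	10.756
1.72056	1163.37	0.0174564	10.6303
1.8092	1047.42	0.0186251	10.5424
1.8092	20296.9	0.0186494	10.5406
1.85924	5900.85	0.0193105	10.4909
1.8716	4696.76	0.0194648	10.4793
1.8716	16974.9	0.01949	10.4774
2.00911	3807.26	0.0213477	10.3375
2.17105	3150.15	0.0235721	10.1697
2.281	2789.49	0.0250739	10.0563
2.281	3267.6	0.0251054	10.0539
2.34605	3035.85	0.025989	9.98718
2.53516	2508.42	0.0286018	9.78952
2.5749	2418.61	0.0291293	9.74957
2.5749	2581.35	0.0291646	9.7469
2.7395	2215.64	0.0313837	9.57867
2.8196	2071.43	0.0324424	9.49831
2.8196	2158.99	0.0324803	9.49544
2.96032	1926.86	0.0343394	9.35418
3.19894	1602.64	0.0374823	9.11495
3.45679	1330.21	0.0408207	8.8602
3.73542	1101.93	0.0443601	8.58941
4.03652	910.756	0.0480617	8.30536
4.36188	751.898	0.0519108	8.00901
4.71347	619.917	0.0559234	7.69897
5.0934	510.375	0.0600969	7.37523
5.50396	419.621	0.0643392	7.04466
5.94761	344.636	0.0686558	6.70661
6.42701	282.79	0.0730483	6.36075
6.94506	231.845	0.0774194	6.01437
7.50487	189.915	0.0817887	5.6657
8.1098	155.433	0.0861025	5.31871
8.7635	127.103	0.0903497	4.974
9.46988	103.768	0.0944962	4.63402
10.2068	85.3264	0.0983727	4.31258
10.2068	234.961	0.0984238	4.30832
10.2332	233.353	0.0985303	4.29943
11.058	184.906	0.102413	3.97308
11.544	164.681	0.104474	3.79782
11.544	228.524	0.104522	3.79375
11.9494	208.351	0.106126	3.65624
12.0998	201.661	0.106683	3.6082
12.0998	232.643	0.106729	3.60421
12.9126	197.458	0.109637	3.35116
13.9534	161.729	0.112917	3.06007
15.0781	132.306	0.115943	2.78466
16.2935	108.077	0.118698	2.52606
17.6068	88.1917	0.121175	2.28485
19.026	71.8916	0.123373	2.06101
20.5596	58.5433	0.125295	1.85404
22.2168	47.6205	0.126951	1.66311
24.0076	38.6976	0.128351	1.48732
25.9428	31.4179	0.129501	1.32591
28.0339	25.4706	0.130411	1.1781
30.2936	20.6294	0.131087	1.04323
32.7354	16.6999	0.131536	0.920763
35.374	13.5119	0.131762	0.810249
38.2253	10.9266	0.131773	0.711113
41.3065	8.83108	0.131576	0.622668
44.636	7.13305	0.131181	0.544139
48.2339	5.75647	0.130598	0.474695
52.1218	4.6426	0.129837	0.413485
56.3231	3.73991	0.12891	0.359677
60.863	3.01195	0.127826	0.312484
65.7689	2.42516	0.126596	0.271166
69.525	2.07905	0.125639	0.245025
69.525	10.6671	0.125621	0.244573
71.0702	10.1098	0.125228	0.235049
76.7989	8.26811	0.123733	0.203521
82.9893	6.74766	0.122119	0.176035
89.6786	5.50357	0.120396	0.152104
96.9072	4.47652	0.11857	0.131295
104.718	3.63841	0.116651	0.113229
113.159	2.95558	0.114648	0.0975647
122.28	2.39957	0.112568	0.0840028
132.137	1.94706	0.11042	0.0722757
142.788	1.57614	0.108211	0.0621479
154.297	1.27164	0.10595	0.05341
166.734	1.0265	0.103645	0.0458789
180.174	0.829025	0.101303	0.0393933
194.697	0.66988	0.098932	0.0338123
210.391	0.541559	0.096539	0.0290128
227.349	0.438041	0.0941307	0.0248879
245.675	0.354492	0.0917137	0.0213444
265.477	0.287025	0.089294	0.0183016
286.876	0.232519	0.086877	0.01569
310	0.188462	0.084468	0.013449
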