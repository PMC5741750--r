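energy_kev	intensity
49.772	53
50.742	93.8
56.95	9.7
57.51	18.7
59.1	6.5
63.12	44.2
93.61	2.57
109.78	17.5
118.19	1.87
130.52	11.38
177.21	22.32
197.96	35.93
261.08	1.76
307.74	10.05
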