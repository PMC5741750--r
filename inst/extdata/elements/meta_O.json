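{
 "symbol": "O",
 "atomic_number": 8,
 "atomic_mass": 15.9994,
 "density": null,
 "shell_binding": {
  "K": 0.5431
 },
 "fluorescence_yield": {},
 "coster_kronig": {},
 "jump_ratios": {},
 "lines": [],
 "auger": [],
 "f0": {
  "s": [
   0.0,
   0.1,
   0.2,
   0.3,
   0.4,
   0.5,
   0.6,
   0.7,
   0.8,
   0.9,
   1.0,
   1.1,
   1.2,
   1.3,
   1.4,
   1.5,
   1.6,
   1.7,
   1.8,
   1.9,
   2.0,
   2.25,
   2.5,
   2.75,
   3.0,
   3.25,
   3.5,
   3.75,
   4.0,
   4.25,
   4.5,
   4.75,
   5.0,
   5.25,
   5.5,
   5.75,
   6.0,
   6.5,
   7.0,
   7.5,
   8.0,
   8.5,
   9.0,
   9.5,
   10.0,
   10.5,
   11.0,
   11.5,
   12.0,
   13.0,
   14.0,
   15.0,
   16.0,
   17.0,
   18.0,
   19.0,
   20.0,
   21.0,
   22.0,
   23.0,
   24.0,
   25.0
  ],
  "value": [
   7.9994,
   7.24524,
   5.62145,
   4.08684,
   3.00189,
   2.33032,
   1.93637,
   1.7014,
   1.55052,
   1.44133,
   1.35055,
   1.26648,
   1.18425,
   1.10248,
   1.02132,
   0.94142,
   0.86352,
   0.78832,
   0.71639,
   0.6482,
   0.58408,
   0.44293,
   0.32947,
   0.24175,
   0.17607,
   0.12808,
   0.09355,
   0.06883,
   0.05107,
   0.03816,
   0.02863,
   0.02148,
   0.01606,
   0.01194,
   0.00879,
   0.0064,
   0.00461,
   0.0023,
   0.00108,
   0.00048,
   0.0002,
   8e-05,
   3e-05,
   1e-05,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0
  ]
 }
}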