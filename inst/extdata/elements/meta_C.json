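{
 "symbol": "C",
 "atomic_number": 6,
 "atomic_mass": 12.0107,
 "density": null,
 "shell_binding": {
  "K": 0.2842
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
   5.9992,
   5.1074,
   3.55867,
   2.49202,
   1.94393,
   1.67986,
   1.52878,
   1.41337,
   1.30623,
   1.19951,
   1.09253,
   0.98678,
   0.88414,
   0.78628,
   0.69452,
   0.60979,
   0.53268,
   0.46345,
   0.40206,
   0.34825,
   0.30157,
   0.21211,
   0.15309,
   0.11459,
   0.08882,
   0.07058,
   0.05677,
   0.04573,
   0.03662,
   0.02903,
   0.02274,
   0.01758,
   0.01341,
   0.01008,
   0.00748,
   0.00547,
   0.00395,
   0.00197,
   0.00093,
   0.00042,
   0.00018,
   7e-05,
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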