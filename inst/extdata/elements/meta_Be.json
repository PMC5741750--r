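{
 "symbol": "Be",
 "atomic_number": 4,
 "atomic_mass": 9.012182,
 "density": 1.848,
 "shell_binding": {
  "K": 0.1115
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
   4.0002,
   3.065,
   2.05941,
   1.6927,
   1.52101,
   1.35931,
   1.19215,
   1.02824,
   0.87519,
   0.73785,
   0.61841,
   0.51694,
   0.43206,
   0.36162,
   0.30323,
   0.25468,
   0.21407,
   0.17988,
   0.15097,
   0.12648,
   0.10576,
   0.06724,
   0.04299,
   0.02828,
   0.01951,
   0.0142,
   0.01079,
   0.00841,
   0.00663,
   0.00521,
   0.00407,
   0.00314,
   0.00239,
   0.0018,
   0.00134,
   0.00098,
   0.00071,
   0.00035,
   0.00017,
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
   0.0,
   0.0,
   0.0
  ]
 }
}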