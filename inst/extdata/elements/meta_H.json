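{
 "symbol": "H",
 "atomic_number": 1,
 "atomic_mass": 1.00794,
 "density": null,
 "shell_binding": {
  "K": 0.0136
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
   0.99995,
   0.85427,
   0.56805,
   0.33108,
   0.18444,
   0.10295,
   0.05938,
   0.0358,
   0.02218,
   0.01387,
   0.00879,
   0.00579,
   0.00411,
   0.00321,
   0.00274,
   0.00249,
   0.00233,
   0.00222,
   0.00212,
   0.00204,
   0.00195,
   0.00173,
   0.00152,
   0.00131,
   0.00112,
   0.00094,
   0.00078,
   0.00064,
   0.00051,
   0.00041,
   0.00032,
   0.00025,
   0.00019,
   0.00014,
   0.00011,
   8e-05,
   6e-05,
   3e-05,
   1e-05,
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
   0.0,
   0.0,
   0.0
  ]
 }
}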