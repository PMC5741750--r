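{
 "symbol": "Al",
 "atomic_number": 13,
 "atomic_mass": 26.981539,
 "density": 2.699,
 "shell_binding": {
  "K": 1.5596
 },
 "fluorescence_yield": {},
 "coster_kronig": {},
 "jump_ratios": {
  "K": 12.166885434032745
 },
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
   12.9937,
   11.22945,
   9.15665,
   7.85947,
   6.74121,
   5.66688,
   4.67594,
   3.82505,
   3.13817,
   2.60818,
   2.2096,
   1.91096,
   1.6832,
   1.50368,
   1.3568,
   1.23273,
   1.12563,
   1.03202,
   0.94967,
   0.87694,
   0.81246,
   0.67964,
   0.57516,
   0.48818,
   0.4126,
   0.34559,
   0.2861,
   0.23379,
   0.18848,
   0.14987,
   0.11753,
   0.0909,
   0.06933,
   0.05215,
   0.03869,
   0.02831,
   0.02042,
   0.0102,
   0.00482,
   0.00215,
   0.00091,
   0.00036,
   0.00014,
   5e-05,
   2e-05,
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
   0.0
  ]
 }
}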