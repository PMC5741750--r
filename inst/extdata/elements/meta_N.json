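{
 "symbol": "N",
 "atomic_number": 7,
 "atomic_mass": 14.0067,
 "density": null,
 "shell_binding": {
  "K": 0.4099
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
   6.9946,
   6.19831,
   4.61089,
   3.33254,
   2.60082,
   2.25576,
   2.14525,
   2.16168,
   2.23937,
   2.34822,
   2.47806,
   2.62632,
   2.79244,
   2.97602,
   3.1764,
   3.3926,
   3.62337,
   3.86716,
   4.12223,
   4.3867,
   4.65856,
   5.35728,
   6.05874,
   6.73577,
   7.36677,
   7.93618,
   8.43412,
   8.8556,
   9.19964,
   9.46835,
   9.66613,
   9.79898,
   9.87378,
   9.89783,
   9.87837,
   9.82226,
   9.73581,
   9.49341,
   9.18674,
   8.84037,
   8.47023,
   8.08636,
   7.6951,
   7.30072,
   6.90636,
   6.51453,
   6.12737,
   5.7468,
   5.37451,
   4.66071,
   3.9959,
   3.38708,
   2.83848,
   2.35177,
   1.92643,
   1.56013,
   1.24916,
   0.98883,
   0.77389,
   0.5988,
   0.45807,
   0.34644
  ]
 }
}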