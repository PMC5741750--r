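{
 "symbol": "Cu",
 "atomic_number": 29,
 "atomic_mass": 63.546,
 "density": 8.96,
 "shell_binding": {
  "K": 8.9789,
  "L1": 1.0961,
  "L2": 0.951,
  "L3": 0.9311,
  "M1": 0.1198,
  "M2": 0.0736,
  "M3": 0.0735,
  "M4": 0.0017,
  "M5": 0.0016,
  "N": 0.0008
 },
 "fluorescence_yield": {
  "K": 0.44
 },
 "coster_kronig": {},
 "jump_ratios": {
  "L1": 1.1112184650701356,
  "K": 8.056889490159692
 },
 "lines": [
  {
   "shell": "K",
   "label": "Ka1",
   "final": "L3",
   "energy": 8.0478,
   "intensity": 1.0
  },
  {
   "shell": "K",
   "label": "Ka2",
   "final": "L2",
   "energy": 8.0279,
   "intensity": 0.51
  },
  {
   "shell": "K",
   "label": "Kb1",
   "final": "M3",
   "energy": 8.9054,
   "intensity": 0.137
  }
 ],
 "auger": [
  {
   "shell": "K",
   "a": "L1",
   "b": "L1",
   "weight": 0.05
  },
  {
   "shell": "K",
   "a": "L1",
   "b": "L2",
   "weight": 0.15
  },
  {
   "shell": "K",
   "a": "L1",
   "b": "L3",
   "weight": 0.12
  },
  {
   "shell": "K",
   "a": "L2",
   "b": "L2",
   "weight": 0.05
  },
  {
   "shell": "K",
   "a": "L2",
   "b": "L3",
   "weight": 0.25
  },
  {
   "shell": "K",
   "a": "L3",
   "b": "L3",
   "weight": 0.1
  },
  {
   "shell": "K",
   "a": "L2",
   "b": "M3",
   "weight": 0.1
  },
  {
   "shell": "K",
   "a": "L3",
   "b": "M3",
   "weight": 0.13
  },
  {
   "shell": "K",
   "a": "M3",
   "b": "M3",
   "weight": 0.05
  },
  {
   "shell": "L1",
   "a": "M3",
   "b": "M5",
   "weight": 1.0
  },
  {
   "shell": "L1ck2",
   "a": "L2",
   "b": "N",
   "weight": 1.0
  },
  {
   "shell": "L1ck3",
   "a": "L3",
   "b": "M5",
   "weight": 1.0
  },
  {
   "shell": "L2",
   "a": "M3",
   "b": "M5",
   "weight": 0.5
  },
  {
   "shell": "L2",
   "a": "M4",
   "b": "M5",
   "weight": 0.5
  },
  {
   "shell": "L2ck3",
   "a": "L3",
   "b": "N",
   "weight": 1.0
  },
  {
   "shell": "L3",
   "a": "M4",
   "b": "M5",
   "weight": 0.4
  },
  {
   "shell": "L3",
   "a": "M3",
   "b": "M5",
   "weight": 0.3
  },
  {
   "shell": "L3",
   "a": "M5",
   "b": "N",
   "weight": 0.3
  },
  {
   "shell": "M1",
   "a": "N",
   "b": "N",
   "weight": 1.0
  },
  {
   "shell": "M2",
   "a": "N",
   "b": "N",
   "weight": 1.0
  },
  {
   "shell": "M3",
   "a": "N",
   "b": "N",
   "weight": 1.0
  },
  {
   "shell": "M4",
   "a": "N",
   "b": "N",
   "weight": 1.0
  },
  {
   "shell": "M5",
   "a": "N",
   "b": "N",
   "weight": 1.0
  }
 ],
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
   28.9859,
   27.09438,
   23.5251,
   19.86926,
   16.48521,
   13.66807,
   11.46715,
   9.80445,
   8.57929,
   7.68935,
   7.03549,
   6.53179,
   6.11386,
   5.73996,
   5.38678,
   5.0434,
   4.70609,
   4.37475,
   4.05076,
   3.736,
   3.4323,
   2.73127,
   2.12557,
   1.621,
   1.21428,
   0.89594,
   0.65313,
   0.47192,
   0.33903,
   0.24282,
   0.17374,
   0.12432,
   0.08897,
   0.06362,
   0.0454,
   0.03227,
   0.0228,
   0.0111,
   0.00519,
   0.00231,
   0.00097,
   0.00039,
   0.00015,
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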