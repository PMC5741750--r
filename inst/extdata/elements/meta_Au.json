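{
 "symbol": "Au",
 "atomic_number": 79,
 "atomic_mass": 196.967,
 "density": 19.32,
 "shell_binding": {
  "K": 80.7249,
  "L1": 14.3528,
  "L2": 13.7336,
  "L3": 11.9187,
  "M1": 3.4249,
  "M2": 3.1478,
  "M3": 2.743,
  "M4": 2.2911,
  "M5": 2.2057,
  "N": 0.5449
 },
 "fluorescence_yield": {
  "K": 0.964,
  "L1": 0.107,
  "L2": 0.334,
  "L3": 0.32
 },
 "coster_kronig": {
  "f12": 0.14,
  "f13": 0.53,
  "f23": 0.122
 },
 "jump_ratios": {
  "M5": 13.61528526402405,
  "M4": 3.372352631122162,
  "M3": 1.158081177119671,
  "M2": 1.0631843304998283,
  "M1": 1.0410553346513207,
  "L3": 2.6170984678766303,
  "L2": 1.3953115467785804,
  "L1": 1.1537976937555066,
  "K": 4.897592844165858
 },
 "lines": [
  {
   "shell": "K",
   "label": "Ka1",
   "final": "L3",
   "energy": 68.8062,
   "intensity": 1.0
  },
  {
   "shell": "K",
   "label": "Ka2",
   "final": "L2",
   "energy": 66.9913,
   "intensity": 0.59
  },
  {
   "shell": "K",
   "label": "Kb1",
   "final": "M3",
   "energy": 77.9819,
   "intensity": 0.227
  },
  {
   "shell": "K",
   "label": "Kb3",
   "final": "M2",
   "energy": 77.5771,
   "intensity": 0.117
  },
  {
   "shell": "K",
   "label": "Kb2",
   "final": "N",
   "energy": 80.18,
   "intensity": 0.083
  },
  {
   "shell": "L1",
   "label": "Lb3",
   "final": "M3",
   "energy": 11.6098,
   "intensity": 0.55
  },
  {
   "shell": "L1",
   "label": "Lb4",
   "final": "M2",
   "energy": 11.205,
   "intensity": 0.45
  },
  {
   "shell": "L2",
   "label": "Lb1",
   "final": "M4",
   "energy": 11.4425,
   "intensity": 0.85
  },
  {
   "shell": "L2",
   "label": "Lg1",
   "final": "N",
   "energy": 13.1887,
   "intensity": 0.15
  },
  {
   "shell": "L3",
   "label": "La1",
   "final": "M5",
   "energy": 9.713,
   "intensity": 0.8
  },
  {
   "shell": "L3",
   "label": "La2",
   "final": "M4",
   "energy": 9.6276,
   "intensity": 0.1
  },
  {
   "shell": "L3",
   "label": "Lb2",
   "final": "N",
   "energy": 11.3738,
   "intensity": 0.1
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
   78.9572,
   75.16653,
   67.20737,
   59.28548,
   52.39234,
   46.57611,
   41.71446,
   37.52651,
   33.77566,
   30.35583,
   27.24876,
   24.46195,
   21.9949,
   19.83087,
   17.94054,
   16.2884,
   14.83835,
   13.55735,
   12.41727,
   11.39532,
   10.47364,
   8.5244,
   6.97338,
   5.72426,
   4.70496,
   3.86082,
   3.15285,
   2.55491,
   2.04983,
   1.62571,
   1.27321,
   0.98408,
   0.75038,
   0.56438,
   0.41866,
   0.30629,
   0.22099,
   0.11035,
   0.05213,
   0.02329,
   0.00985,
   0.00394,
   0.00149,
   0.00053,
   0.00018,
   6e-05,
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
   0.0
  ]
 }
}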