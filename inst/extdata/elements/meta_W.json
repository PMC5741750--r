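{
 "symbol": "W",
 "atomic_number": 74,
 "atomic_mass": 183.84,
 "density": 19.3,
 "shell_binding": {
  "K": 69.525,
  "L1": 12.0998,
  "L2": 11.544,
  "L3": 10.2068,
  "M1": 2.8196,
  "M2": 2.5749,
  "M3": 2.281,
  "M4": 1.8716,
  "M5": 1.8092,
  "N": 0.425
 },
 "fluorescence_yield": {
  "K": 0.958,
  "L1": 0.147,
  "L2": 0.27,
  "L3": 0.255
 },
 "coster_kronig": {
  "f12": 0.16,
  "f13": 0.28,
  "f23": 0.133
 },
 "jump_ratios": {
  "M5": 19.377913175487194,
  "M4": 3.6141840854395895,
  "M3": 1.1713969727899072,
  "M2": 1.0672874788644746,
  "M1": 1.0422721442770138,
  "L3": 2.753667271302596,
  "L2": 1.3876776143255252,
  "L1": 1.1536310999657593,
  "K": 5.130761011763506
 },
 "lines": [
  {
   "shell": "K",
   "label": "Ka1",
   "final": "L3",
   "energy": 59.3182,
   "intensity": 1.0
  },
  {
   "shell": "K",
   "label": "Ka2",
   "final": "L2",
   "energy": 57.981,
   "intensity": 0.58
  },
  {
   "shell": "K",
   "label": "Kb1",
   "final": "M3",
   "energy": 67.244,
   "intensity": 0.222
  },
  {
   "shell": "K",
   "label": "Kb3",
   "final": "M2",
   "energy": 66.9501,
   "intensity": 0.114
  },
  {
   "shell": "K",
   "label": "Kb2",
   "final": "N",
   "energy": 69.1,
   "intensity": 0.077
  },
  {
   "shell": "L1",
   "label": "Lb3",
   "final": "M3",
   "energy": 9.8188,
   "intensity": 0.55
  },
  {
   "shell": "L1",
   "label": "Lb4",
   "final": "M2",
   "energy": 9.5249,
   "intensity": 0.45
  },
  {
   "shell": "L2",
   "label": "Lb1",
   "final": "M4",
   "energy": 9.6724,
   "intensity": 0.85
  },
  {
   "shell": "L2",
   "label": "Lg1",
   "final": "N",
   "energy": 11.119,
   "intensity": 0.15
  },
  {
   "shell": "L3",
   "label": "La1",
   "final": "M5",
   "energy": 8.3976,
   "intensity": 0.8
  },
  {
   "shell": "L3",
   "label": "La2",
   "final": "M4",
   "energy": 8.3352,
   "intensity": 0.1
  },
  {
   "shell": "L3",
   "label": "Lb2",
   "final": "N",
   "energy": 9.7818,
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
   73.95182,
   69.81256,
   62.43057,
   55.47652,
   49.03274,
   43.38763,
   38.56655,
   34.37737,
   30.66894,
   27.38589,
   24.51776,
   22.05044,
   19.94933,
   18.16306,
   16.63351,
   15.30488,
   14.12935,
   13.06947,
   12.09817,
   11.19721,
   10.35512,
   8.47022,
   6.87054,
   5.53437,
   4.43527,
   3.54033,
   2.81536,
   2.22907,
   1.75505,
   1.3721,
   1.06352,
   0.81616,
   0.61941,
   0.46448,
   0.34392,
   0.25134,
   0.18123,
   0.09045,
   0.04272,
   0.01909,
   0.00807,
   0.00323,
   0.00122,
   0.00044,
   0.00015,
   5e-05,
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
   0.0
  ]
 }
}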