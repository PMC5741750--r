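{
 "symbol": "Er",
 "atomic_number": 68,
 "atomic_mass": 167.259,
 "density": 9.066,
 "shell_binding": {
  "K": 57.4855,
  "L1": 9.7513,
  "L2": 9.2643,
  "L3": 8.3579,
  "M1": 2.2065,
  "M2": 2.0058,
  "M3": 1.8118,
  "M4": 1.4533,
  "M5": 1.4093,
  "N": 0.2756
 },
 "fluorescence_yield": {
  "K": 0.933,
  "L1": 0.085,
  "L2": 0.188,
  "L3": 0.187
 },
 "coster_kronig": {
  "f12": 0.19,
  "f13": 0.28,
  "f23": 0.157
 },
 "jump_ratios": {
  "M5": 25.839562466243162,
  "M4": 3.629119210510897,
  "M3": 1.1703580226540937,
  "M2": 1.06715976860629,
  "M1": 1.0432768863952728,
  "L3": 2.8484370387056264,
  "L2": 1.3928261599779341,
  "L1": 1.153309492607847,
  "K": 5.4028173818376
 },
 "lines": [
  {
   "shell": "K",
   "label": "Ka1",
   "final": "L3",
   "energy": 49.1276,
   "intensity": 1.0
  },
  {
   "shell": "K",
   "label": "Ka2",
   "final": "L2",
   "energy": 48.2212,
   "intensity": 0.56
  },
  {
   "shell": "K",
   "label": "Kb1",
   "final": "M3",
   "energy": 55.6737,
   "intensity": 0.213
  },
  {
   "shell": "K",
   "label": "Kb3",
   "final": "M2",
   "energy": 55.4797,
   "intensity": 0.11
  },
  {
   "shell": "K",
   "label": "Kb2",
   "final": "N",
   "energy": 57.2099,
   "intensity": 0.066
  },
  {
   "shell": "L1",
   "label": "Lb3",
   "final": "M3",
   "energy": 7.9395,
   "intensity": 0.55
  },
  {
   "shell": "L1",
   "label": "Lb4",
   "final": "M2",
   "energy": 7.7455,
   "intensity": 0.45
  },
  {
   "shell": "L2",
   "label": "Lb1",
   "final": "M4",
   "energy": 7.811,
   "intensity": 0.85
  },
  {
   "shell": "L2",
   "label": "Lg1",
   "final": "N",
   "energy": 8.9887,
   "intensity": 0.15
  },
  {
   "shell": "L3",
   "label": "La1",
   "final": "M5",
   "energy": 6.9486,
   "intensity": 0.8
  },
  {
   "shell": "L3",
   "label": "La2",
   "final": "M4",
   "energy": 6.9046,
   "intensity": 0.1
  },
  {
   "shell": "L3",
   "label": "Lb2",
   "final": "N",
   "energy": 8.0823,
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
   67.96549,
   63.8002,
   57.18316,
   50.29892,
   43.94752,
   38.63756,
   34.20725,
   30.40028,
   27.09884,
   24.27651,
   21.91299,
   19.96054,
   18.34836,
   16.99808,
   15.83707,
   14.806,
   13.86127,
   12.97384,
   12.1264,
   11.31004,
   10.52131,
   8.6721,
   7.01921,
   5.5849,
   4.37506,
   3.38022,
   2.58033,
   1.94951,
   1.4601,
   1.08544,
   0.80169,
   0.58858,
   0.42956,
   0.31155,
   0.22442,
   0.16042,
   0.11369,
   0.05545,
   0.02587,
   0.01149,
   0.00484,
   0.00193,
   0.00073,
   0.00026,
   9e-05,
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
   0.0
  ]
 }
}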