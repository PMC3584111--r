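{
  "n_specimens": 4,
  "specimen_ids": ["CVH-1", "CVH-2", "CVH-4", "CVH-5"],
  "landmarks": {
    "AC": [0, 11.85, 0],
    "PC": [0, -11.85, 0],
    "PU_A_L": [-15.80, 28.38, 0],
    "PU_A_R": [15.63, 28.78, 0],
    "PU_L_L": [-28.68, 0, 0],
    "PU_L_R": [28.40, 0, 0],
    "OX": [0, 18.60, -17.20],
    "RN_L": [-4.65, -5.93, -6.38],
    "RN_R": [4.43, -5.90, -6.40]
  },
  "third_ventricle_width": 0.99,
  "stn": {
    "left": {
      "x": [-13.85, -4.96],
      "y": [-5.47, 4.24],
      "z": [-7.22, -0.76],
      "gravity": [-9.63, -1.05, -3.95]
    },
    "right": {
      "x": [5.38, 13.89],
      "y": [-5.23, 4.41],
      "z": [-7.19, -0.66],
      "gravity": [9.83, -0.65, -3.75]
    }
  }
}
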