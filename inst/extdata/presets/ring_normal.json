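{
  "model": "ring",
  "rhythm": "normal",
  "params": {
    "nodes": {
      "SA": {"a": 3, "w1": 0.2, "w2": -1.9, "d": 3, "e": 4.5, "rho": 1,  "omega": 0},
      "AV": {"a": 3, "w1": 0.1, "w2": -0.1, "d": 3, "e": 3,   "rho": 1,  "omega": 0},
      "HP": {"a": 5, "w1": 1, "w2": -1, "d": 3, "e": 7,   "rho": 20, "omega": 0}
    },
    "k":   {"SA_AV": 0, "SA_HP": 0, "AV_SA": 5,   "AV_HP": 0, "HP_SA": 0, "HP_AV": 20},
    "tau": {"SA_AV": 0, "SA_HP": 0, "AV_SA": 0.8, "AV_HP": 0, "HP_SA": 0, "HP_AV": 0},
    "alpha": [1, 0.1, 0.05, 0.4],
    "beta_G": 0.0012
  },
  "time_scale": 16,
  "gain": 1.0,
  "notes": "Sinus rhythm; ring of three delay-coupled oscillators, normal parameter row. HP-node oscillator coefficients are synthetic defaults (not tabulated)."
}
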