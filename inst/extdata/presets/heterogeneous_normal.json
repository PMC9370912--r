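{
  "model": "heterogeneous",
  "rhythm": "normal",
  "params": {
    "pacemakers": {
      "SA": {"a": 40, "u": 0.69, "f": 22, "d": 3, "e": 3.5, "K": 0, "tau": 0},
      "AV": {"a": 50, "u": 0.69, "f": 8.4, "d": 3, "e": 5, "K": 22, "tau": 0.092},
      "HP": {"a": 50, "u": 0.69, "f": 1.5, "d": 3, "e": 12, "K": 22, "tau": 0.092}
    },
    "muscles": {
      "P":   {"k": 2000,  "c": 0.26, "w1": 0.13, "w2": 1.0, "b": 0,     "g": 0.4,  "h": 0.004, "C": 4e-05},
      "Ta":  {"k": 100,   "c": 0.12, "w1": 0.12, "w2": 1.1, "b": 0,     "g": 0.09, "h": 0.008, "C": -4e-05},
      "QRS": {"k": 10000, "c": 0.12, "w1": 0.12, "w2": 1.1, "b": 0.015, "g": 0.09, "h": 0.008, "C": 9e-05},
      "T":   {"k": 2000,  "c": 0.1,  "w1": 0.22, "w2": 0.8, "b": 0,     "g": 0.1,  "h": 0.008, "C": -6e-05}
    },
    "z0": 0.2
  },
  "time_scale": 1,
  "gain": 1.0,
  "notes": "Sinus rhythm; heterogeneous conduction-system network, normal parameter row."
}
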