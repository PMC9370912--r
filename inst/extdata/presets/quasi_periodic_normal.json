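{
  "model": "quasi_periodic",
  "rhythm": "normal",
  "params": {
    "kernels": {
      "Pminus": {"a": 0,    "b": 0.25, "theta": "-pi/3"},
      "Pplus":  {"a": 1.2,  "b": 0.25, "theta": "-pi/3"},
      "Q":      {"a": -0.5, "b": 0.1,  "theta": "-pi/12"},
      "R":      {"a": 30,   "b": 0.1,  "theta": "0"},
      "S":      {"a": -7.5, "b": 0.1,  "theta": "pi/12"},
      "Tminus": {"a": 0,    "b": 0.75, "theta": "pi/2"},
      "Tplus":  {"a": 0.75, "b": 0.45, "theta": "pi/2"}
    },
    "hr": 60, "A": 0.005, "fr": 0.25
  },
  "time_scale": 1,
  "gain": 1.0,
  "notes": "Sinus rhythm; quasi-periodic Gaussian-kernel model, normal kernel table, 60 bpm."
}
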