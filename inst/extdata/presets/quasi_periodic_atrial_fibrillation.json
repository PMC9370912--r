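{
  "model": "quasi_periodic",
  "rhythm": "atrial_fibrillation",
  "params": {
    "kernels": {
      "Pminus": {"a": 0.7,  "b": 0.12, "theta": "-5*pi/7"},
      "Pplus":  {"a": 0.9,  "b": 0.13, "theta": "-pi/2"},
      "Q":      {"a": 0.6,  "b": 0.12, "theta": "-pi/4"},
      "R":      {"a": 18,   "b": 0.1,  "theta": "0"},
      "S":      {"a": -0.1, "b": 0.05, "theta": "-pi/30"},
      "Tminus": {"a": 0.62, "b": 0.15, "theta": "pi/4"},
      "Tplus":  {"a": 0.55, "b": 0.17, "theta": "7*pi/11"}
    },
    "hr": 100, "A": 0.005, "fr": 0.25,
    "tachogram": {"hr_mean": 100, "hr_std": 15}
  },
  "time_scale": 1,
  "gain": 1.0,
  "notes": "Atrial fibrillation kernel table; irregular beat-to-beat intervals drawn from a seeded RR tachogram (mean 100 bpm, sd 15)."
}
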