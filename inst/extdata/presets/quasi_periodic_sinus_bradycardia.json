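{
  "model": "quasi_periodic",
  "rhythm": "sinus_bradycardia",
  "params": {
    "kernels": {
      "Pminus": {"a": 0.7,  "b": 0.2,  "theta": "-3*pi/8"},
      "Pplus":  {"a": 0.8,  "b": 0.1,  "theta": "-pi/3"},
      "Q":      {"a": -1,   "b": 0.1,  "theta": "-pi/13"},
      "R":      {"a": 20,   "b": 0.1,  "theta": "0"},
      "S":      {"a": -9.5, "b": 0.1,  "theta": "pi/15"},
      "Tminus": {"a": 0.27, "b": 0.4,  "theta": "2*pi/5"},
      "Tplus":  {"a": 0.15, "b": 0.55, "theta": "4*pi/7"}
    },
    "hr": 45, "A": 0.005, "fr": 0.25
  },
  "time_scale": 1,
  "gain": 1.0,
  "notes": "Sinus bradycardia kernel table; default 45 bpm (slow regular rhythm below 60 bpm)."
}
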