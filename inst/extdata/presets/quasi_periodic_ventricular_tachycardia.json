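{
  "model": "quasi_periodic",
  "rhythm": "ventricular_tachycardia",
  "params": {
    "kernels": {
      "Pminus": {"a": 1,   "b": 0.2,  "theta": "10*pi/13"},
      "Pplus":  {"a": 1,   "b": 0.1,  "theta": "-2*pi/3"},
      "Q":      {"a": -12, "b": 0.2,  "theta": "-pi/3"},
      "R":      {"a": 1,   "b": 0.3,  "theta": "0"},
      "S":      {"a": 3,   "b": 0.4,  "theta": "2*pi/11"},
      "Tminus": {"a": 5,   "b": 0.5,  "theta": "pi/2"},
      "Tplus":  {"a": 3,   "b": 0.45, "theta": "2*pi/23"}
    },
    "hr": 150, "A": 0.005, "fr": 0.25
  },
  "time_scale": 1,
  "gain": 1.0,
  "notes": "Ventricular tachycardia kernel table; default 150 bpm (ventricular rate above 120 bpm)."
}
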