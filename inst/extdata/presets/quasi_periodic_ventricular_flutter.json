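{
  "model": "quasi_periodic",
  "rhythm": "ventricular_flutter",
  "params": {
    "kernels": {
      "Pminus": {"a": 0,   "b": 0.1, "theta": "-pi/6"},
      "Pplus":  {"a": 0,   "b": 0.1, "theta": "-2*pi/3"},
      "Q":      {"a": 0,   "b": 0.1, "theta": "-pi/12"},
      "R":      {"a": 20,  "b": 0.6, "theta": "-pi/2"},
      "S":      {"a": -20, "b": 0.6, "theta": "pi/2"},
      "Tminus": {"a": 0,   "b": 0.1, "theta": "3*pi/8"},
      "Tplus":  {"a": 0,   "b": 0.1, "theta": "5*pi/8"}
    },
    "hr": 270, "A": 0.005, "fr": 0.25
  },
  "time_scale": 1,
  "gain": 1.0,
  "notes": "Ventricular flutter kernel table (sine-wave-like, no distinct QRS/T); default 270 bpm, within the 250-300 bpm flutter band."
}
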