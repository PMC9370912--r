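{
  "model": "ring",
  "rhythm": "ventricular_fibrillation",
  "base": "normal",
  "params": {
    "nodes": {
      "SA": {"e": 6, "omega": 7.33},
      "AV": {"omega": 7.33},
      "HP": {"omega": 7.33}
    },
    "k": {"AV_SA": 5, "HP_AV": 20},
    "beta_G": 0.0012
  },
  "time_scale": 16,
  "gain": 1.0,
  "notes": "Ventricular fibrillation row: sinusoidal drives switched on at frequency 7.33, SA cubic root widened."
}
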