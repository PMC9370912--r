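{
  "model": "ring",
  "rhythm": "sinus_bradycardia",
  "base": "normal",
  "params": {"k": {"AV_SA": 5, "HP_AV": 15}, "beta_G": 0.0009},
  "time_scale": 8,
  "gain": 1.0,
  "notes": "Sinus bradycardia row: weakened HP coupling, time-scale factor 8, reduced output scale."
}
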