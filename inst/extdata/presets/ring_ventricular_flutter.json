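{
  "model": "ring",
  "rhythm": "ventricular_flutter",
  "base": "normal",
  "params": {"k": {"AV_SA": 0, "HP_AV": 20}, "beta_G": 0.0012},
  "time_scale": 8,
  "gain": 1.0,
  "notes": "Ventricular flutter row: AV-to-SA coupling removed, time-scale factor 8."
}
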