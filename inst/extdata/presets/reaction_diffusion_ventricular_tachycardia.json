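{
  "model": "reaction_diffusion",
  "rhythm": "ventricular_tachycardia",
  "base": "normal",
  "params": {"H": 2.178, "K": [0, 0, 0, -0.1]},
  "time_scale": 21,
  "gain": 1.0,
  "notes": "Ventricular tachycardia row: H and mixing weights changed, time-scale factor 21."
}
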