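{
  "model": "reaction_diffusion",
  "rhythm": "ventricular_flutter",
  "base": "normal",
  "params": {"H": 2.178, "K": [0.1, -0.02, -0.01, 0]},
  "time_scale": 13,
  "gain": 1.0,
  "notes": "Ventricular flutter row: H and mixing weights changed, time-scale factor 13."
}
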