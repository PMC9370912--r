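{
  "model": "reaction_diffusion",
  "rhythm": "atrial_flutter",
  "base": "normal",
  "params": {"H": 1.52, "K": [0.068, 0.028, 0.024, 0.012]},
  "time_scale": 13,
  "gain": 1.0,
  "notes": "Atrial flutter row: H and mixing weights changed, time-scale factor 13."
}
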