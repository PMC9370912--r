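{
  "model": "reaction_diffusion",
  "rhythm": "normal",
  "params": {
    "H": 3, "C": 1.35, "beta": 4,
    "K": [-0.024, 0.0216, -0.0012, 0.12]
  },
  "time_scale": 7,
  "gain": 1.0,
  "notes": "Sinus rhythm; discretized reaction-diffusion network, normal parameter row."
}
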