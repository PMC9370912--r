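{
  "model": "heterogeneous",
  "rhythm": "complete_AV_HP_block",
  "base": "normal",
  "params": {"pacemakers": {"HP": {"K": 0}}},
  "time_scale": 1,
  "gain": 1.0,
  "notes": "Complete AV-HP block: AV-to-His-Purkinje coupling set to zero; ventricles escape at a slow rate."
}
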