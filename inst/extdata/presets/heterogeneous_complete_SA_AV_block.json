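{
  "model": "heterogeneous",
  "rhythm": "complete_SA_AV_block",
  "base": "normal",
  "params": {"pacemakers": {"AV": {"K": 0}}},
  "time_scale": 1,
  "gain": 1.0,
  "notes": "Complete SA-AV block: SA-to-AV coupling constant set to zero; atria and ventricles decouple."
}
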