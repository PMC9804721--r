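{
  "fixture": "meltdown_calibrated",
  "T_from": 0, "T_to": 40, "T_step": 0.05
}
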