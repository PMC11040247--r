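{
  "epsilon": 0.175,
  "noise": {"type": "ambiguity", "level": 0.13},
  "init": "six_americas",
  "seed": 7,
  "snapshot_every": 5000
}
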