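{
  "epsilon_values": [0.05, 0.175, 0.3],
  "nu_values": [1e-10, 0.08, 0.18],
  "noise_types": ["ambiguity"],
  "replicates": 50,
  "base": {
    "init": "six_americas",
    "seed": 1
  }
}
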