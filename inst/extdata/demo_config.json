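{
  "design": {
    "n_per_group": 2,
    "groups": ["dance", "active"],
    "times": ["pre", "post"],
    "effect_spec": {"dance_post": {"coupling_gain": 0.85}},
    "seed": 42
  },
  "n_nodes": 16,
  "fs": 125,
  "duration": 10.24,
  "epoch_len": 256,
  "densities": [40],
  "n_nulls": 20,
  "compute_local": true,
  "seed": 42
}
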