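{
  "task": "imt",
  "preset": "rc-14",
  "algorithm": "random_committee",
  "n_features": 14,
  "negative_sampling": "all",
  "seed": 1
}
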