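{
  "task": "act",
  "preset": "NBM-12-400-td",
  "algorithm": "nbm",
  "selection_method": "chi2",
  "orders": [1, 2],
  "k": 400,
  "training_split": "train_plus_dev",
  "seed": 1
}
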