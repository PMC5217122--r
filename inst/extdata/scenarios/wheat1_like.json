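{
  "n": 599,
  "m": 4,
  "p": 1279,
  "maf_range": [0.05, 0.5],
  "UE_true": [
    [0.7, -0.0133, -0.133, -0.084],
    [-0.0133, 0.7, 0.4627, 0.2877],
    [-0.133, 0.4627, 0.7, 0.2716],
    [-0.084, 0.2877, 0.2716, 0.7]
  ],
  "FE_true": [
    [0.1, 0.0, 0.0, 0.0],
    [0.0, 0.1, 0.05, 0.03],
    [0.0, 0.05, 0.1, 0.03],
    [0.0, 0.03, 0.03, 0.1]
  ],
  "Sigma_true": [0.3, 0.3, 0.3, 0.3],
  "architecture": "additive",
  "seed": 1
}
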