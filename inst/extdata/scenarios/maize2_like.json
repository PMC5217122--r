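{
  "n": 504,
  "m": 3,
  "p": 2000,
  "maf_range": [0.05, 0.5],
  "UE_true": [
    [0.7, 0.2716, 0.1834],
    [0.2716, 0.7, 0.1071],
    [0.1834, 0.1071, 0.7]
  ],
  "Sigma_true": [0.3, 0.3, 0.3],
  "architecture": "additive",
  "seed": 2
}
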