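{
  "N": 1000,
  "t_split": 1667,
  "g": 100,
  "alpha_P": 0.246,
  "mu": 1.2e-08,
  "rec": 1.3e-08,
  "n_segments": 300,
  "segment_length": 1e+06
}
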