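{
  "simulate": {
    "n_segments": 60,
    "target_count": 1800,
    "selected": {"segment": 30, "position": 5e+05, "s": 0.03}
  },
  "k": 5,
  "generations": 100,
  "n_null_runs": 0
}
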