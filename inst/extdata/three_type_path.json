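{
  "alpha": [1.1, 1.0, 1.1],
  "beta": [0.8, 0.9, 0.5],
  "nu": [0.01, 0.01, 0],
  "labels": ["founder", "intermediate", "double-mutant"],
  "tie_tol": 1e-9
}
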