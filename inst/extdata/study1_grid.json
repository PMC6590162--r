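{
  "comment": "full coverage-study grid: binomial tables, estimated variances, (30,50,100,150,300) size pattern",
  "mu": [0, 0.25, 0.5, 0.75, 1],
  "tau": [0, 0.1, 0.2, 0.3, 0.4, 0.5],
  "pi_c": [0.1, 0.3, 0.5],
  "k": [5, 10, 20, 40, 160],
  "reps": 10000,
  "seed": 1,
  "variance_mode": "estimated",
  "generator_mode": "binomial"
}
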