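{
  "comment": "exact-variance comparison: constant study size 30, enumeration-exact variances",
  "mu": [0],
  "tau": [0, 0.1, 0.2, 0.3, 0.4, 0.5],
  "pi_c": [0.1, 0.5],
  "k": [5, 40, 160],
  "size": 30,
  "reps": 3000,
  "seed": 1,
  "variance_mode": "exact",
  "generator_mode": "binomial"
}
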