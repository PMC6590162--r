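{
  "comment": "heat-map grid over k and pi_c at a constant per-group size of 30",
  "mu": [0],
  "tau": [0, 0.5],
  "pi_c": [0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.5],
  "k": [5, 10, 20, 40, 80, 160],
  "size": 30,
  "reps": 10000,
  "seed": 1,
  "variance_mode": "estimated",
  "generator_mode": "binomial"
}
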