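{
  "comment": "Synthetic population config example: a severe, C5-dominated cohort with weaker spontaneous recovery than the package default.",
  "ml_marginals": {"C5": 0.55, "C6": 0.2, "C7": 0.1, "C8": 0.08, "T1": 0.07},
  "concordance": 2.5,
  "at_ml_weights": [4, 6, 10, 25, 30, 25],
  "spared_prob": [0.25, 0.18, 0.1, 0.06],
  "baseline_pool_size": 40,
  "coefficients": {
    "cutpoints": [0.2, 1.4, 2.4, 3.4, 4.6],
    "lev_dist_step": -0.6,
    "lev_ml_step": -0.2,
    "base_step": 0.5,
    "auto_step": 0.45
  }
}
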