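{
  "alpha": 0.3,
  "beta": 15,
  "lapse": 0.02,
  "bias_side": 1,
  "bias_strength": 0,
  "latency_median_correct_s": 8.6,
  "latency_sigma": 0.4,
  "latency_ratio_incorrect": 3,
  "fatigue_trials": 100,
  "learning_rate": 0,
  "family": "logistic",
  "seed": 1
}
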