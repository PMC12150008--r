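{
  "K": 4,
  "d": 250,
  "n_arm": 250,
  "clength": 100,
  "M": 3,
  "pattern": "linear",
  "lambda": 0.5,
  "models": ["fixed_period", "spline_period_q3", "ttest_pooled", "ttest_separate"]
}
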