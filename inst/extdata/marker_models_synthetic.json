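{
  "label": "synthetic fixture parameters (not the published ref-8 models); aligned with the synthetic cohort generator's case/control distributions",
  "mom": {
    "median_ks": 55,
    "median_at": 100
  },
  "tapping": {
    "mean_case": [-0.25, 0.35],
    "mean_control": [0, 0],
    "cov_case": [
      [0.0625, -0.015],
      [-0.015, 0.09]
    ],
    "cov_control": [
      [0.04, -0.01],
      [-0.01, 0.0225]
    ]
  },
  "smell16": {
    "intercept": -10.175975,
    "coefficients": {
      "banana": 1.996554,
      "chocolate": 1.832088,
      "cinnamon": 1.820916,
      "clove": 1.81529,
      "coconut": 1.774606,
      "dill_pickle": 1.738271,
      "gasoline": 1.74597,
      "licorice": 1.717018,
      "mint": 1.691172,
      "onion": 1.709068,
      "orange": 1.730391,
      "pineapple": 1.755215,
      "rose": 1.728044,
      "soap": 1.709263,
      "smoke": 1.698233,
      "turpentine": 1.694596
    },
    "training_prevalence": 0.5
  },
  "smell6": {
    "intercept": -3.148265,
    "coefficients": {
      "banana": 1.996554,
      "chocolate": 1.832088,
      "cinnamon": 1.820916,
      "clove": 1.81529,
      "coconut": 1.774606,
      "dill_pickle": 1.738271
    },
    "training_prevalence": 0.5
  },
  "thresholds": {
    "motor_ks": -0.2,
    "motor_at": 0.25,
    "smell_errors": 5
  },
  "odour_error_control": {
    "banana": 0.1,
    "chocolate": 0.12,
    "cinnamon": 0.13,
    "clove": 0.14,
    "coconut": 0.15,
    "dill_pickle": 0.16,
    "gasoline": 0.17,
    "licorice": 0.18,
    "mint": 0.19,
    "onion": 0.2,
    "orange": 0.21,
    "pineapple": 0.22,
    "rose": 0.24,
    "soap": 0.26,
    "smoke": 0.28,
    "turpentine": 0.3
  },
  "odour_error_case": {
    "banana": 0.45,
    "chocolate": 0.46,
    "cinnamon": 0.48,
    "clove": 0.5,
    "coconut": 0.51,
    "dill_pickle": 0.52,
    "gasoline": 0.54,
    "licorice": 0.55,
    "mint": 0.56,
    "onion": 0.58,
    "orange": 0.6,
    "pineapple": 0.62,
    "rose": 0.64,
    "soap": 0.66,
    "smoke": 0.68,
    "turpentine": 0.7
  }
}
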