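{
  "version": "predict-pd-factor-tables-1.0",
  "notes": "Likelihood ratios / odds ratios per risk factor for the three algorithm variants. lr_neg = null marks factors with no published negative likelihood ratio (no prevalence data): known absence leaves risk unchanged. The enhanced depression/anxiety LR- is 0.87 (the MDS catalogue prints 0.88) and never-smoked is 1.25 (MDS 1.2), as catalogued.",
  "enhanced": {
    "sex": { "male": 1.2, "female": 0.8 },
    "factors": {
      "coffee":               { "lr_pos": 0.88, "lr_neg": 1.35 },
      "current_smoker":       { "lr_pos": 0.51, "lr_neg": null },
      "former_smoker":        { "lr_pos": 0.91, "lr_neg": null },
      "never_smoked":         { "lr_pos": 1.25, "lr_neg": null },
      "relative_pd":          { "lr_pos": 2.5,  "lr_neg": null },
      "constipation":         { "lr_pos": 2.5,  "lr_neg": 0.82 },
      "erectile_dysfunction": { "lr_pos": 3.4,  "lr_neg": 0.87 },
      "depression_anxiety":   { "lr_pos": 1.6,  "lr_neg": 0.87 },
      "pesticides":           { "lr_pos": 1.5,  "lr_neg": null },
      "diabetes":             { "lr_pos": 1.50, "lr_neg": 0.97 },
      "head_injury":          { "lr_pos": 1.55, "lr_neg": 0.98 },
      "nsaid":                { "lr_pos": 0.96, "lr_neg": 1.16 },
      "ccb":                  { "lr_pos": 0.94, "lr_neg": 1.04 },
      "beta_blocker":         { "lr_pos": 1.19, "lr_neg": 0.93 },
      "alcohol":              { "lr_pos": 0.98, "lr_neg": 1.09 },
      "rbd":                  { "lr_pos": 2.8,  "lr_neg": 0.89 }
    }
  },
  "basic": {
    "sex": { "male": 1.0, "female": 0.67 },
    "factors": {
      "coffee":               { "or": 0.67 },
      "current_smoker":       { "or": 0.44 },
      "former_smoker":        { "or": 0.78 },
      "relative_pd":          { "or": 3.2 },
      "constipation":         { "or": 2.3 },
      "erectile_dysfunction": { "or": 3.8 },
      "depression_anxiety":   { "or": 1.86 },
      "head_injury":          { "or": 1.58 },
      "nsaid":                { "or": 0.83 },
      "ccb":                  { "or": 0.9 },
      "beta_blocker":         { "or": 1.28 },
      "alcohol":              { "or": 0.9 }
    }
  },
  "mds": {
    "sex": { "male": 1.2, "female": 0.8 },
    "factors": {
      "coffee":               { "lr_pos": 0.88, "lr_neg": 1.35 },
      "current_smoker":       { "lr_pos": 0.51, "lr_neg": null },
      "former_smoker":        { "lr_pos": 0.91, "lr_neg": null },
      "never_smoked":         { "lr_pos": 1.2,  "lr_neg": null },
      "relative_pd":          { "lr_pos": 2.5,  "lr_neg": null },
      "constipation":         { "lr_pos": 2.5,  "lr_neg": 0.82 },
      "erectile_dysfunction": { "lr_pos": 3.4,  "lr_neg": 0.87 },
      "depression_anxiety":   { "lr_pos": 1.6,  "lr_neg": 0.88 },
      "pesticides":           { "lr_pos": 1.5,  "lr_neg": null },
      "diabetes":             { "lr_pos": 1.50, "lr_neg": 0.97 },
      "rbd":                  { "lr_pos": 2.8,  "lr_neg": 0.89 }
    },
    "markers": {
      "motor": { "lr_pos": 3.5, "lr_neg": 0.60 },
      "smell": { "lr_pos": 4.0, "lr_neg": 0.43 }
    }
  }
}
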