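# predictpd

Risk-algorithm toolkit for **prodromal Parkinson's disease (PD)** screening
in longitudinal survey cohorts. It is aimed at epidemiologists and movement
disorder researchers who estimate an individual's risk of future PD from
remotely administered tests — demographic and exposure questions, an odour
identification panel, a keyboard tapping task and an RBD screening
questionnaire — and who need to compare algorithm variants, track risk over
survey waves, and validate scores against incident diagnoses.

## The model

Risk is carried as odds in favour of PD and updated multiplicatively with
likelihood ratios (LRs), assuming independence of factors:

```
odds(posterior) = odds(age) × LR_sex × Π_k LR_k(factor k) × LR_smell × LR_tap × LR_RBD
```

* **Age prior** — a continuous equation, `odds = 1 : (22.098 + 78.900
  e^(−0.14053 (age − 60)))`, strictly increasing from 1:101 at age 60 to
  1:27 at age 80.
* **Dichotomous factors** (smoking status, coffee, constipation, erectile
  dysfunction, depression/anxiety, family history, pesticides, diabetes,
  head injury, NSAID/CCB/beta-blocker/alcohol use, RBD) contribute LR+ when
  present, LR− when absent and 1 when unknown. Factors published only as
  odds ratios are converted with prevalence data via
  `LR+ = OR/((1−prev) + prev·OR)`, `LR− = 1/((1−prev) + prev·OR)`.
* **Continuous markers** — smell enters as a logistic-regression score over
  a 16- or 6-odour panel, expressed as posterior-over-prior odds; tapping
  enters as the case/control bivariate-Gaussian density ratio of delta
  multiple-of-the-median kinesia score and akinesia time.

Three variants are provided: the **enhanced** LR algorithm (continuous
markers, 16- or 6-item smell panel), the older **basic** algorithm (odds
ratios, applied only when a factor is present, markers excluded), and an
**MDS-style** variant (LR catalogue subset with dichotomised motor/smell
markers). Around the scorer sit a longitudinal pipeline (carry-forward
imputation of skipped waves, smell-test carry rules, centile/fold-difference
summaries, log-scale histograms), a synthetic cohort generator with
risk-dependent incident PD, and validation statistics (Cox proportional
hazards of incident PD on baseline risk; regression of striatal DaT-SPECT
binding on log risk with a bootstrap R² interval).

## Worked example

Score a 72-year-old male, former smoker, with constipation, no coffee use,
no probable RBD, and a slow tapping result (44 taps, 128 ms akinesia time):

```r
library(predictpd)
w <- list(age = 72, sex = "male", constipation = "P", coffee = "A",
          current_smoker = "A", former_smoker = "P", never_smoked = "A",
          rbd = "A", ks_raw = 44, at_raw = 128)
compute_risk(w, algorithm_variant("enhanced16"))
#> PD risk (enhanced16, survey year 0): 1:4.9 (odds 0.204557)
#>   breakdown: prior=0.02724, sex=1.2, coffee=1.35, former_smoker=0.91,
#>              constipation=2.5, rbd=0.89, tapping=2.289
```

The age prior (1:36.7) is multiplied by the male sex LR, the LR− for absent
coffee use (absence of a protective exposure raises risk), the LR+ for
constipation, the LR− for absent RBD, and a tapping LR of 2.3 from the
impaired motor performance. The basic variant, by contrast, only multiplies
odds ratios of *present* factors and ignores the markers:

```r
compute_risk(w[1:8], algorithm_variant("basic"))
#> PD risk (basic, survey year 0): 1:20 (odds 0.0488699)
#>   breakdown: prior=0.02724, former_smoker=0.78, constipation=2.3
```

A full synthetic-cohort round trip — simulate, impute, score, summarise,
validate:

```r
sim <- simulate_cohort(simulation_config(n_participants = 500), seed = 42)
sc  <- score_cohort(impute_cohort(sim$waves), algorithm_variant("enhanced16"))
summarize_cohort(sc)[1, c("n", "fold_90_10", "fold_75_25")]
#>     n fold_90_10 fold_75_25
#> 1 500   12488.98   179.5663

m <- merge(sc[sc$survey_year == 0, ], sim$outcomes, by = "participant_id")
cox_fit(m$log_odds, m$event, m$time)
#> Cox PH: 15 events / 500 participants
#>   HR per 10-fold risk increase: 1.62 (1.31-2.00)
#>   HR per SD of log risk:        2.27 (1.59-3.24)
#>   Wald p = 6.98e-06 (LRT p = 0.000204)
```

The fold differences show the enhanced algorithm spreading risk over several
orders of magnitude across the cohort, and the Cox fit recovers the
generator's planted association between baseline risk and incident PD
(hazard roughly doubling per SD of log risk).

A thin command-line wrapper with `simulate`, `score`, `summarize` and
`validate` subcommands lives at `inst/cli/predictpd.R`.

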