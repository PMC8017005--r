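---
title: "Methods: likelihood-ratio risk estimation for prodromal Parkinson's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-ratio risk estimation for prodromal Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predictpd)
```

## The model and its assumptions

The package estimates an individual's odds of developing Parkinson's
disease (PD) during the prodromal window by sequential Bayesian updating on
the odds scale. A continuous age-based prior odds is multiplied by one
likelihood ratio (LR) per risk factor or marker:

$$\mathrm{odds} = \mathrm{odds}(\mathrm{age}) \times LR_{\mathrm{sex}}
  \times \prod_k LR_k \times LR_{\mathrm{smell}} \times LR_{\mathrm{tap}}
  \times LR_{\mathrm{RBD}}.$$

The central assumption is conditional independence of factors given disease
status — the same naive-Bayes assumption underlying the MDS prodromal
research criteria. It is certainly imperfect in reality (smoking and coffee
use correlate; depression and constipation co-occur), and the product
should be read as a first-approximation ranking device rather than a
calibrated probability. Risk is kept as odds, not probability: odds are
unbounded above, so the heavy upper tail that drives enrichment decisions
stays visible, and log-odds histograms are less skewed.

Working on the odds scale makes each update literal multiplication, and
every estimate carries a per-factor breakdown whose product reconstructs
the final odds to machine precision (`compute_risk()$breakdown`), so any
score can be audited factor by factor.

### The age prior

$$\mathrm{odds}(\mathrm{age}) = 1 : \left(22.098 + 78.900\,
  e^{-0.14053\,(\mathrm{age}-60)}\right)$$

rises strictly from 1:101 at age 60 towards an asymptote of 1:22.1, giving
1:27 at age 80. The equation is a continuous fit through age-category odds;
because it was fitted on ages 60–90 we clamp (with a warning) rather than
extrapolate outside `[60, 90]`. The MDS-style variant can instead use a
piecewise-constant 5-year-interval prior; no interval table ships with the
package because no canonical numeric table is available, so categorical
mode requires user configuration — when none is supplied the variant is
constructed with the continuous equation instead (`age_mode = "equation"`),
which keeps the variant runnable end to end and is the documented default
fallback.

### Dichotomous factors

Each factor is three-state: present (multiply LR+), absent (multiply LR−),
unknown (multiply 1). Factors published only as odds ratios were converted
with exposure prevalence:

$$LR^+ = \frac{OR}{(1-p) + p\,OR}, \qquad
  LR^- = \frac{1}{(1-p) + p\,OR},$$

which imply two identities used as invariants throughout the test suite:
$LR^+/LR^- = OR$ and $p\,LR^+ + (1-p)\,LR^- = 1$. Factors with no
prevalence data (pesticide exposure, first-degree relative with PD) have no
LR−; they are stored with a unit placeholder and a `no_lr_neg` flag so
known absence leaves risk unchanged. Smoking is an exclusive three-state
exposure (current/former/never), each state carrying only an LR+; erectile
dysfunction is inapplicable to females and always contributes 1 for them.
The enhanced catalogue prints depression/anxiety LR− = 0.87 where the MDS
catalogue prints 0.88, and never-smoked 1.25 versus 1.2; both are carried
as printed, per variant.

The basic (odds-ratio) variant multiplies an OR only when a factor is
recorded *present* — known absence carries no information under that
algorithm — and applies 0.67 for female sex only. This asymmetry, not any
difference in the factor list, is the main reason the basic algorithm
produces a much narrower risk distribution.

### Continuous markers

**Tapping.** Raw kinesia score (KS, taps per fixed interval) and akinesia
time (AT, ms) are standardised to delta multiple-of-the-median,
$x/\mathrm{median} - 1$, so the reference median maps to 0 and the control
population centres at the origin. The formula is chosen to match MoM
screening practice; whether "difference from the median" is taken before or
after MoM scaling is not canonically fixed, and this definition makes the
two equivalent up to the scale of the median. The LR is the ratio of two
bivariate normal densities (cases over controls) evaluated at the
participant's (ΔKS, ΔAT) point. The 2×2 density is computed in closed form;
an independent density implementation (`mclust::dmvnorm`) serves as the
test oracle.

**Smell.** A logistic regression over a fixed odour panel (16 items, or
the 6 most discriminant) with items coded 1 when identified *incorrectly*
(hyposmia is the risk marker). The LR is posterior odds over training
prior odds, $LR = \frac{p/(1-p)}{\pi/(1-\pi)}$ with $p$ the logistic
probability and $\pi$ the training prevalence, so an uninformative response
pattern gives exactly 1.

The published coefficients of the real case-control smell and tapping
models are not reprinted here; they are **required configuration** for real
cohorts. The shipped parameter file
(`inst/extdata/marker_models_synthetic.json`) is a clearly labelled
synthetic fixture whose logistic coefficients are the naive-Bayes values
implied by the generator's per-odour error probabilities
($\beta_j = \log\frac{q_{1j}(1-q_{0j})}{q_{0j}(1-q_{1j})}$), so package
code, tests and simulations are mutually consistent.

**RBD** stays dichotomous (LR+ 2.8 / LR− 0.89): questionnaire-based RBD and
mood items add little predictive information once the odour panel is
included, so no continuous RBD model is built.

**Dichotomisation (MDS-style variant).** Motor impairment is "present" when
ΔKS falls strictly below −0.2 or ΔAT rises strictly above +0.25; olfactory
impairment when more than 5 of 16 odours are missed. Equality at a
threshold counts as absent — the strict convention is fixed explicitly so
tests are deterministic. These thresholds are defaults in the synthetic
fixture, roughly one control SD in the impaired direction, and are
configuration for real data.

## The cohort pipeline

Survey waves are indexed 0–4 and 6 (no data exist for year 5, and the
pipeline will never fabricate a year-5 record). Imputation is deliberately
simple carry-forward, mirroring how the cohort data were handled:

* gaps strictly between observed waves copy the preceding wave's exposures
  with age incremented one year per survey year;
* nothing is imputed after a participant's last observed wave;
* smell tests happen only at baseline and year 3: baseline responses apply
  to years 1–2, year-3 responses to years 4 and 6; a missing source test
  means no smell data (multiplier 1) for its target years;
* pesticide exposure, first asked at year 3, is back-filled to earlier
  waves.

Imputed waves are flagged (`completed = FALSE`) and excluded from completed
survey counts. The operation is idempotent. No attempt is made at multiple
imputation; the rules are deterministic by design, so uncertainty from
imputation is not propagated.

Distribution summaries report the 1st, 2.5th, 10th, 25th, 50th, 75th, 90th,
95th, 97.5th and 99th centiles of odds per survey year, and the 90th/10th
and 75th/25th fold differences. Extreme fold differences (min/max, 1st/99th)
are avoided: with continuous markers in the score they are outlier-driven.
Quantiles use linear interpolation of order statistics at position
$p(n-1)+1$ (R's type 7) — the convention is fixed so fold differences are
bit-for-bit reproducible. Histograms use log10-uniform bins aligned to
decade boundaries, default 5 bins per decade (a presentation choice only).

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the algorithms assume, not PD
biology: n = 1,323 by default, baseline ages uniform on 60–80, 60.9%
female, independent baseline exposures at realistic prevalences (the five
medication/injury factors use their published prevalence data: head injury
0.03, NSAID 0.80, CCB 0.43, beta blocker 0.28, alcohol 0.80; the rest are
plausible values for a UK population of this age), a 2% prodromal fraction
whose tapping and odour responses come from the case distributions, 5%
wave-skip and 8% per-wave dropout, smell-test completion of 67% at baseline
and 60% at year 3, and a small (2%) per-wave exposure transition noise.
Incident PD is exponential time-to-event with hazard
$h_0 e^{\beta z}$, $h_0 = 0.005$/year and $\beta = \log 2$ per SD of the
standardised true baseline log risk, detected at the first completed survey
after onset and censored at the last completed wave — the simplest model
that exercises interval-censored detection and the Cox stage.

What passing tests on this generator show — and do not show: they verify
the algebra, the missing-data semantics, the qualitative spread ordering
(basic narrowest, enhanced widest) and parameter recovery of the validation
stage. They do not certify real-data performance: real exposures are
correlated, real smell/tapping models are flatter than the synthetic
fixture (the synthetic enhanced-variant fold differences are accordingly
larger than those seen in a real cohort), and real dropout is informative.

## Validation statistics

The Cox stage regresses time to incident PD on baseline natural-log odds
with Efron tie handling (events land on yearly survey boundaries, so ties
are expected); fitting is delegated to `survival::coxph`, and the test
suite checks the maximiser against a brute-force, written-out partial
likelihood on toy data. The single coefficient is reported as HR per
10-fold risk increase ($e^{\hat\beta \ln 10}$) and HR per SD of log risk
($e^{\hat\beta s}$), with Wald CIs and p-value (an LR-test p-value is
reported alongside, since which of the two a published table uses is often
unstated). Time origin is the baseline survey; a constant covariate returns
HR 1 by convention rather than an error.

The imaging stage takes the lower of the two bilateral striatal binding
ratios as the depletion marker, regresses it on log odds by OLS, and
bootstraps the R² (percentile interval, 5,000 participant resamples by
default, seed-deterministic). Percentile rather than BCa is used — the
simplest method consistent with a bootstrap of stated size. A quadratic
F-test probes non-linearity. Scans are paired to the year-2/3 risk
estimate, preferring waves with observed (non-imputed) data and breaking
ties towards the earlier wave.

## Numerical conventions and problem sizes

All arithmetic is double precision; "1:N" rounding (integer N at ≥10, one
decimal below) is presentation-only. Reference-table reproduction is
asserted after rounding to the printed 2 decimals; algebraic identities at
1e−12; the Cox-vs-brute-force comparison at 1e−6. Simulation-based checks
in the test suite use n = 400–3,000 participants, 50 replicates for planted
hazard-ratio coverage and 200 for the null size of the Wald test — sizes
chosen to put Monte-Carlo error well inside the asserted tolerances while
the whole suite runs in well under a minute.

## Known limitations

* Independence of factors is assumed throughout; an explicit correlation
  hook in the generator is the only concession to dependence.
* The shipped marker coefficients are synthetic; real-cohort scoring
  requires externally fitted smell/tapping models and reference medians.
* The basic variant's original age equation is not available (only its
  age-80 value is known), so the basic variant reuses the revised equation
  by default.
* Carry-forward imputation understates within-participant variability.
* The Cox stage supports a single baseline covariate by design — no
  time-varying covariates or competing risks.
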