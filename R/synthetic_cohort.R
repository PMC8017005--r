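# draw one bivariate normal sample per row via Cholesky
.rbvn <- function(n, mean, sigma) {
  z <- matrix(stats::rnorm(2 * n), n, 2)
  z %*% chol(sigma) + matrix(mean, n, 2, byrow = TRUE)
}

#' Simulation configuration for a synthetic cohort
#'
#' Defines the study conditions the generator emulates: a healthy 60-80
#' year-old baseline cohort (default n = 1,323; 60.9% female) followed with
#' annual online surveys over 7 years with no year-5 data collection,
#' smell testing at baseline and year 3 only, pesticide exposure asked
#' from year 3 onwards, keyboard tapping at every survey, occasional
#' skipped waves and permanent dropout, and incident PD arising from an
#' exponential time-to-event whose log hazard is linear in the
#' participant's standardised true log risk.
#'
#' Exposure prevalences default to the factor catalogue's prevalence data
#' where published (head injury 0.03, NSAID 0.80, CCB 0.43, beta blocker
#' 0.28, alcohol 0.80); the remaining prevalences are realistic values for
#' a UK population of this age.
#'
#' @param n_participants cohort size at baseline.
#' @param age_range baseline age range in years (uniform draw).
#' @param prop_female proportion of females.
#' @param prevalence named vector of baseline exposure prevalences.
#' @param prodromal_fraction fraction of the cohort in the prodromal phase
#'   (markers drawn from the case distributions).
#' @param waves survey years simulated (year 5 must be absent).
#' @param p_skip probability a wave is skipped but the participant returns.
#' @param p_dropout per-wave probability of permanent dropout.
#' @param p_flip per-wave probability a known exposure status toggles
#'   (small transition noise).
#' @param p_smell_baseline,p_smell_year3 completion probabilities of the
#'   odour panel at baseline / year 3.
#' @param p_tapping completion probability of the tapping task per wave.
#' @param p_rbd prevalence of probable RBD.
#' @param h0 baseline hazard of PD per year.
#' @param beta log-hazard coefficient per SD of true log risk
#'   (default log 2: a doubling of hazard per SD).
#' @param models marker/config bundle used both to draw markers and to
#'   define the "true" baseline risk (enhanced 16-odour variant).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 1323,
                              age_range = c(60, 80),
                              prop_female = 0.609,
                              prevalence = c(
                                coffee = 0.65, current_smoker = 0.10,
                                former_smoker = 0.35, relative_pd = 0.05,
                                constipation = 0.15,
                                erectile_dysfunction = 0.30,
                                depression_anxiety = 0.15,
                                pesticides = 0.10, diabetes = 0.09,
                                head_injury = 0.03, nsaid = 0.80,
                                ccb = 0.43, beta_blocker = 0.28,
                                alcohol = 0.80),
                              prodromal_fraction = 0.02,
                              waves = c(0L, 1L, 2L, 3L, 4L, 6L),
                              p_skip = 0.05,
                              p_dropout = 0.08,
                              p_flip = 0.02,
                              p_smell_baseline = 0.67,
                              p_smell_year3 = 0.60,
                              p_tapping = 0.90,
                              p_rbd = 0.05,
                              h0 = 0.005,
                              beta = log(2),
                              models = NULL) {
  probs <- c(prevalence, prodromal_fraction, p_skip, p_dropout, p_flip,
             p_smell_baseline, p_smell_year3, p_tapping, p_rbd, prop_female)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_participants < 1) stop("need n_participants >= 1", call. = FALSE)
  if (h0 <= 0) stop("baseline hazard must be positive", call. = FALSE)
  if (5L %in% waves) stop("year 5 has no data collection", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants), age_range = age_range,
         prop_female = prop_female, prevalence = prevalence,
         prodromal_fraction = prodromal_fraction,
         waves = sort(as.integer(waves)), p_skip = p_skip,
         p_dropout = p_dropout, p_flip = p_flip,
         p_smell_baseline = p_smell_baseline,
         p_smell_year3 = p_smell_year3, p_tapping = p_tapping,
         p_rbd = p_rbd, h0 = h0, beta = beta, models = models),
    class = "simulation_config"
  )
}

#' Simulate a synthetic longitudinal cohort
#'
#' Draws a reproducible cohort under the given configuration. Exposures
#' are drawn independently at baseline and carried across waves with small
#' transition noise. Markers come from the control bivariate-Gaussian /
#' odour-error distributions unless the participant is prodromal, in which
#' case the case distributions apply. Incident PD times are exponential
#' with hazard \eqn{h_0 e^{\beta z}}, where z is the standardised true log
#' risk (enhanced 16-odour variant at baseline); diagnoses are detected at
#' the first completed survey at or after the event time, and follow-up is
#' censored at the last completed survey.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; identical config + seed give an identical
#'   cohort.
#' @return list with `waves` (observed participant-wave data.frame) and
#'   `outcomes` (per participant: `pd_diagnosis_year`, `true_prodromal`,
#'   `time`, `event`, `true_log_risk`, `last_wave`).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  models <- config$models %||% default_marker_models()
  n <- config$n_participants
  ids <- sprintf("P%05d", seq_len(n))
  age0 <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  prodromal <- stats::runif(n) < config$prodromal_fraction

  # baseline exposures: P/A per factor, smoking as exclusive three-state
  draw_status <- function(p) ifelse(stats::runif(n) < p, "P", "A")
  expo <- list()
  for (f in setdiff(names(config$prevalence),
                    c("current_smoker", "former_smoker"))) {
    expo[[f]] <- draw_status(config$prevalence[[f]])
  }
  u <- stats::runif(n)
  p_cur <- config$prevalence[["current_smoker"]]
  p_for <- config$prevalence[["former_smoker"]]
  smoking <- ifelse(u < p_cur, "current",
                    ifelse(u < p_cur + p_for, "former", "never"))
  expo$current_smoker <- ifelse(smoking == "current", "P", "A")
  expo$former_smoker <- ifelse(smoking == "former", "P", "A")
  expo$never_smoked <- ifelse(smoking == "never", "P", "A")
  expo$erectile_dysfunction[sex == "female"] <- "A"
  expo$rbd <- draw_status(config$p_rbd)

  # markers: stable participant-level latent values
  tap_model <- models$tapping
  dm <- matrix(NA_real_, n, 2)
  if (any(!prodromal)) {
    dm[!prodromal, ] <- .rbvn(sum(!prodromal), tap_model$mean_control,
                              tap_model$cov_control)
  }
  if (any(prodromal)) {
    dm[prodromal, ] <- .rbvn(sum(prodromal), tap_model$mean_case,
                             tap_model$cov_case)
  }
  # keep raw values positive: delta MoM is bounded below by -1
  dm <- pmax(dm, -0.95)
  ks_raw <- models$mom$median_ks * (1 + dm[, 1])
  at_raw <- models$mom$median_at * (1 + dm[, 2])

  odours <- names(models$smell16$coefficients)
  err <- matrix(rep(models$odour_error_control[odours], each = n), n)
  if (any(prodromal)) {
    err[prodromal, ] <- rep(models$odour_error_case[odours],
                            each = sum(prodromal))
  }
  resp <- matrix(as.numeric(matrix(stats::runif(n * length(odours)),
                                   n) >= err), n)
  colnames(resp) <- paste0("odour_", odours)

  # participation: baseline always completed; afterwards skip or drop out
  waves <- config$waves
  present <- matrix(FALSE, n, length(waves))
  present[, 1] <- TRUE
  active <- rep(TRUE, n)
  for (k in seq_along(waves)[-1]) {
    active <- active & (stats::runif(n) >= config$p_dropout)
    present[, k] <- active & (stats::runif(n) >= config$p_skip)
  }

  rows <- vector("list", length(waves))
  status_names <- c(setdiff(names(config$prevalence),
                            c("current_smoker", "former_smoker")),
                    "current_smoker", "former_smoker", "never_smoked", "rbd")
  cur <- expo
  for (k in seq_along(waves)) {
    y <- waves[k]
    if (k > 1L) {
      # transition noise on non-smoking dichotomous exposures
      for (f in setdiff(status_names, c(.SMOKING_FACTORS, "rbd"))) {
        flip <- stats::runif(n) < config$p_flip
        cur[[f]][flip] <- ifelse(cur[[f]][flip] == "P", "A", "P")
      }
      cur$erectile_dysfunction[sex == "female"] <- "A"
    }
    df <- data.frame(participant_id = ids, survey_year = y,
                     age = age0 + y, sex = sex, stringsAsFactors = FALSE)
    for (f in status_names) df[[f]] <- cur[[f]]
    if (y < 3L) df$pesticides <- "U"  # not asked before year 3
    smell_here <- if (y == 0L) {
      stats::runif(n) < config$p_smell_baseline
    } else if (y == 3L) {
      stats::runif(n) < config$p_smell_year3
    } else rep(FALSE, n)
    rmat <- resp
    rmat[!smell_here, ] <- NA_real_
    df <- cbind(df, as.data.frame(rmat))
    tap_here <- stats::runif(n) < config$p_tapping
    df$ks_raw <- ifelse(tap_here, ks_raw, NA_real_)
    df$at_raw <- ifelse(tap_here, at_raw, NA_real_)
    df$completed <- TRUE
    rows[[k]] <- df[present[, k], , drop = FALSE]
  }
  all_waves <- do.call(rbind, rows)
  all_waves <- all_waves[order(all_waves$participant_id,
                               all_waves$survey_year), , drop = FALSE]
  rownames(all_waves) <- NULL

  # true baseline risk (markers included regardless of test completion)
  base <- rows[[1]]
  base <- base[order(base$participant_id), , drop = FALSE]
  base[, colnames(resp)] <- resp
  base$ks_raw <- ks_raw
  base$at_raw <- at_raw
  base$pesticides <- expo$pesticides   # true status, even if unasked
  truth <- score_cohort(base, algorithm_variant("enhanced16"), models)
  log_risk <- truth$log_odds
  z <- if (n >= 2 && stats::sd(log_risk) > 0) {
    (log_risk - mean(log_risk)) / stats::sd(log_risk)
  } else rep(0, n)

  haz <- config$h0 * exp(config$beta * z)
  t_pd <- stats::rexp(n, rate = haz)
  last_wave <- apply(present, 1L, function(p) max(waves[p]))
  diag_year <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    detect <- waves[present[i, ] & waves >= t_pd[i]]
    if (length(detect)) diag_year[i] <- min(detect)
  }
  event <- !is.na(diag_year)
  outcomes <- data.frame(
    participant_id = ids,
    true_prodromal = prodromal,
    true_log_risk = log_risk,
    pd_diagnosis_year = diag_year,
    last_wave = last_wave,
    time = ifelse(event, diag_year, last_wave),
    event = event,
    stringsAsFactors = FALSE
  )
  # participants with an event at baseline get a minimal positive follow-up
  outcomes$time <- pmax(outcomes$time, 0.5)

  list(waves = all_waves, outcomes = outcomes)
}

#' Planted-effect recovery check
#'
#' Simulation harness for the Cox validation stage: simulates replicate
#' cohorts with a known log-hazard coefficient per SD of log risk, fits the
#' Cox model on baseline risk via [cox_fit()], and reports how often the
#' 95% CI of the HR per SD covers the planted hazard ratio.
#'
#' @param config a [simulation_config()]; `config$beta` is the planted
#'   log-HR per SD of true log risk.
#' @param n_replicates number of replicate cohorts.
#' @param seed integer seed (replicate r uses seed + r).
#' @param variant algorithm variant used for scoring (default enhanced16).
#' @return list with `coverage` (fraction of CIs covering exp(beta)),
#'   `hr_estimates`, `ci_low`, `ci_high`, `p_values`, `n_events`.
#' @export
planted_effect_check <- function(config, n_replicates = 20L, seed = 1L,
                                 variant = algorithm_variant("enhanced16")) {
  hr_true <- exp(config$beta)
  models <- config$models %||% default_marker_models()
  hr <- lo <- hi <- pv <- ev <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_cohort(config, seed = seed + r)
    base <- sim$waves[sim$waves$survey_year == 0L, , drop = FALSE]
    sc <- score_cohort(base, variant, models)
    m <- merge(sc, sim$outcomes, by = "participant_id")
    fit <- cox_fit(m$log_odds, m$event, m$time)
    hr[r] <- fit$hr_per_sd["estimate"]
    lo[r] <- fit$hr_per_sd["ci_low"]
    hi[r] <- fit$hr_per_sd["ci_high"]
    pv[r] <- fit$p_value
    ev[r] <- fit$n_events
  }
  list(coverage = mean(lo <= hr_true & hr_true <= hi),
       hr_true = hr_true, hr_estimates = hr, ci_low = lo, ci_high = hi,
       p_values = pv, n_events = ev)
}
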