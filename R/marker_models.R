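#' Multiple-of-the-median transform for tapping markers
#'
#' Reference medians for the keyboard-tapping kinesia score (KS, taps per
#' fixed interval) and akinesia time (AT, ms). Raw values are standardised
#' to delta multiple-of-the-median (MoM): `raw/median - 1`, so the
#' reference median maps to 0 and a doubling maps to +1. Centring at the
#' median puts the control population near the origin, where the case and
#' control Gaussians of the tapping model are anchored.
#'
#' @param median_ks reference median kinesia score (taps, > 0).
#' @param median_at reference median akinesia time (ms, > 0).
#' @return object of class `mom_transform`.
#' @export
mom_transform <- function(median_ks, median_at) {
  if (!is.finite(median_ks) || median_ks <= 0 ||
      !is.finite(median_at) || median_at <= 0) {
    stop("reference medians must be positive", call. = FALSE)
  }
  structure(list(median_ks = median_ks, median_at = median_at),
            class = "mom_transform")
}

#' Delta MoM coordinates for a tapping measurement
#'
#' @param ks_raw raw kinesia score(s), taps (> 0).
#' @param at_raw raw akinesia time(s), ms (> 0).
#' @param transform a [mom_transform()].
#' @return numeric matrix with columns `delta_ks`, `delta_at` (one row per
#'   measurement); a single measurement still returns a 1x2 matrix.
#' @examples
#' to_delta_mom(55, 110, mom_transform(50, 100))  # (0.1, 0.1)
#' @export
to_delta_mom <- function(ks_raw, at_raw, transform) {
  stopifnot(inherits(transform, "mom_transform"))
  if (any(!is.finite(ks_raw)) || any(ks_raw <= 0) ||
      any(!is.finite(at_raw)) || any(at_raw <= 0)) {
    stop("raw KS and AT values must be positive", call. = FALSE)
  }
  cbind(delta_ks = ks_raw / transform$median_ks - 1,
        delta_at = at_raw / transform$median_at - 1)
}

#' Bivariate Gaussian likelihood-ratio model for tapping
#'
#' The tapping likelihood ratio is the ratio of two bivariate normal
#' densities evaluated at a participant's (delta KS MoM, delta AT MoM)
#' point: the density fitted to PD cases over the density fitted to
#' controls. PD cases tap more slowly (lower KS) with longer dwell times
#' (higher AT), so their mean sits down-left/up-right of the control mean
#' at the origin.
#'
#' @param mean_case,mean_control length-2 numeric means (delta KS, delta AT).
#' @param cov_case,cov_control 2x2 symmetric positive-definite covariances.
#' @return object of class `bivariate_lr_model`.
#' @export
bivariate_lr_model <- function(mean_case, mean_control, cov_case, cov_control) {
  chk_mean <- function(m, nm) {
    if (length(m) != 2L || any(!is.finite(m))) {
      stop(sprintf("'%s' must be a finite 2-vector", nm), call. = FALSE)
    }
    as.numeric(m)
  }
  chk_cov <- function(s, nm) {
    s <- as.matrix(s)
    if (!all(dim(s) == c(2L, 2L)) || any(!is.finite(s)) ||
        abs(s[1, 2] - s[2, 1]) > 1e-12) {
      stop(sprintf("'%s' must be a finite symmetric 2x2 matrix", nm),
           call. = FALSE)
    }
    det_s <- s[1, 1] * s[2, 2] - s[1, 2]^2
    if (s[1, 1] <= 0 || det_s <= 0) {
      stop(sprintf("'%s' is not positive-definite", nm), call. = FALSE)
    }
    s
  }
  structure(
    list(mean_case = chk_mean(mean_case, "mean_case"),
         mean_control = chk_mean(mean_control, "mean_control"),
         cov_case = chk_cov(cov_case, "cov_case"),
         cov_control = chk_cov(cov_control, "cov_control")),
    class = "bivariate_lr_model"
  )
}

# log-density of a bivariate normal, vectorised over rows of x (n x 2)
.ldbvn <- function(x, mean, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[1, 2], sigma[1, 1]),
                2, 2) / det_s
  d1 <- x[, 1] - mean[1]
  d2 <- x[, 2] - mean[2]
  q <- inv[1, 1] * d1^2 + 2 * inv[1, 2] * d1 * d2 + inv[2, 2] * d2^2
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

#' Tapping likelihood ratio
#'
#' Density ratio (case density / control density) of the bivariate normal
#' model at the given delta-MoM point(s).
#'
#' @param delta_mom a length-2 vector or an n x 2 matrix of
#'   (delta KS MoM, delta AT MoM).
#' @param model a [bivariate_lr_model()].
#' @return positive numeric likelihood ratio(s).
#' @export
tapping_lr <- function(delta_mom, model) {
  stopifnot(inherits(model, "bivariate_lr_model"))
  x <- if (is.matrix(delta_mom)) delta_mom else matrix(delta_mom, ncol = 2L)
  if (ncol(x) != 2L || any(!is.finite(x))) {
    stop("'delta_mom' must be finite with two coordinates", call. = FALSE)
  }
  unname(exp(.ldbvn(x, model$mean_case, model$cov_case) -
               .ldbvn(x, model$mean_control, model$cov_control)))
}

#' Logistic smell likelihood-ratio model
#'
#' Likelihood ratio for olfaction from a logistic-regression score over a
#' fixed odour panel (16-item or 6-item UPSIT subset). Each item is scored
#' as an impairment indicator (1 = odour identified incorrectly). For a
#' response pattern with linear score \eqn{s = intercept + \sum \beta_j x_j},
#' the LR is the posterior odds divided by the training prior odds:
#' \deqn{LR = \frac{p/(1-p)}{\pi/(1-\pi)}, \quad p = logit^{-1}(s)}
#' with \eqn{\pi} the case prevalence in the model's training data, so a
#' response pattern carrying no information (posterior = prior) gives
#' LR = 1.
#'
#' @param intercept logistic intercept.
#' @param coefficients named numeric vector, one coefficient per odour;
#'   the names define the panel.
#' @param training_prevalence case prevalence \eqn{\pi} in (0, 1) of the
#'   model's training sample.
#' @return object of class `logistic_smell_model`.
#' @export
logistic_smell_model <- function(intercept, coefficients, training_prevalence) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("'coefficients' must be named by odour", call. = FALSE)
  }
  if (!is.finite(training_prevalence) ||
      training_prevalence <= 0 || training_prevalence >= 1) {
    stop("'training_prevalence' must lie in (0, 1)", call. = FALSE)
  }
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 training_prevalence = training_prevalence),
            class = "logistic_smell_model")
}

#' Smell likelihood ratio from odour-panel responses
#'
#' @param responses named numeric vector (or n x p matrix with odour column
#'   names), coded 1 = correct identification, 0 = incorrect. The item set
#'   must match the model's panel exactly.
#' @param model a [logistic_smell_model()].
#' @return positive numeric likelihood ratio(s).
#' @export
smell_lr <- function(responses, model) {
  stopifnot(inherits(model, "logistic_smell_model"))
  items <- names(model$coefficients)
  x <- if (is.matrix(responses)) responses else
    matrix(responses, nrow = 1L, dimnames = list(NULL, names(responses)))
  have <- colnames(x)
  missing_items <- setdiff(items, have)
  extra_items <- setdiff(have, items)
  if (length(missing_items) || length(extra_items)) {
    stop(sprintf("odour panel mismatch; missing: [%s]; extra: [%s]",
                 paste(missing_items, collapse = ", "),
                 paste(extra_items, collapse = ", ")), call. = FALSE)
  }
  if (any(!x %in% c(0, 1))) {
    stop("responses must be coded 0 (incorrect) / 1 (correct)", call. = FALSE)
  }
  incorrect <- 1 - x[, items, drop = FALSE]
  s <- model$intercept + as.vector(incorrect %*% model$coefficients)
  prior_logodds <- log(model$training_prevalence /
                         (1 - model$training_prevalence))
  exp(s - prior_logodds)   # posterior odds / prior odds on the log scale
}

#' RBD likelihood ratio
#'
#' Dichotomous REM-sleep behaviour disorder marker (screening
#' questionnaire): present carries LR+ = 2.8, absent LR- = 0.89, unknown
#' contributes the no-information multiplier 1.
#'
#' @param rbd_status character vector in `"P"` (present), `"A"` (absent),
#'   `"U"` (unknown).
#' @return numeric multiplier(s).
#' @export
rbd_lr <- function(rbd_status) {
  status_multiplier(rbd_status, lr_pos = 2.8, lr_neg = 0.89)
}

# three-state P/A/U -> multiplier lookup shared by all dichotomous factors
status_multiplier <- function(status, lr_pos, lr_neg) {
  status[is.na(status)] <- "U"
  if (!all(status %in% c("P", "A", "U"))) {
    stop("status must be one of \"P\", \"A\", \"U\"", call. = FALSE)
  }
  out <- rep(1, length(status))
  out[status == "P"] <- lr_pos
  out[status == "A"] <- lr_neg
  out
}

#' Dichotomise continuous markers for the MDS-style variant
#'
#' Maps the continuous tapping and smell measurements onto three-state
#' present/absent/unknown markers. The convention is strict: a value
#' strictly beyond its threshold is "present"; equality counts as
#' "absent". Unknown (missing) measurements propagate as `"U"`.
#'
#' Motor impairment is present when delta KS MoM falls strictly below
#' `motor_ks` (slower tapping) or delta AT MoM rises strictly above
#' `motor_at` (longer dwell). Olfactory impairment is present when the
#' number of incorrectly identified odours strictly exceeds `smell_errors`.
#'
#' @param delta_mom length-2 vector (delta KS, delta AT) or `NULL` when the
#'   tapping test is missing.
#' @param smell_responses named 0/1 vector of odour responses (1 = correct)
#'   or `NULL` when no smell test is available.
#' @param thresholds list with components `motor_ks`, `motor_at`,
#'   `smell_errors`.
#' @return named character vector `c(motor = , smell = )` with values
#'   `"P"`, `"A"` or `"U"`.
#' @export
dichotomise_markers <- function(delta_mom, smell_responses, thresholds) {
  if (is.null(thresholds) ||
      !all(c("motor_ks", "motor_at", "smell_errors") %in% names(thresholds))) {
    stop("dichotomisation thresholds (motor_ks, motor_at, smell_errors) ",
         "must be supplied for the MDS-style variant", call. = FALSE)
  }
  motor <- if (is.null(delta_mom) || any(is.na(delta_mom))) "U" else {
    if (delta_mom[1] < thresholds$motor_ks ||
        delta_mom[2] > thresholds$motor_at) "P" else "A"
  }
  smell <- if (is.null(smell_responses) || all(is.na(smell_responses))) "U" else {
    n_err <- sum(1 - smell_responses, na.rm = TRUE)
    if (n_err > thresholds$smell_errors) "P" else "A"
  }
  c(motor = motor, smell = smell)
}
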