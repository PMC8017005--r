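#' Cox proportional-hazards fit of incident PD on baseline log risk
#'
#' Fits a Cox model of time to incident PD (censoring at the last completed
#' survey) on the baseline log risk score, with Efron handling of tied
#' event times (events are recorded at yearly survey resolution, so ties
#' are expected). The single fitted coefficient \eqn{\beta} (per unit of
#' natural-log odds) is reported on two scales:
#' \deqn{HR_{10fold} = e^{\beta \ln 10}, \qquad HR_{SD} = e^{\beta s}}
#' where s is the sample SD of the log risk, with Wald 95% CIs and p-value
#' (a likelihood-ratio p-value is reported alongside).
#'
#' @param log_risk numeric, natural-log baseline odds per participant.
#' @param event logical/0-1 incident-PD indicator.
#' @param time positive follow-up time (years to diagnosis or censoring).
#' @return object of class `cox_result`: `beta`, `se`, `hr_per_10fold`,
#'   `hr_per_sd` (each `c(estimate, ci_low, ci_high)`), `p_value`,
#'   `p_value_lrt`, `n`, `n_events`, `sd_log_risk`.
#' @export
cox_fit <- function(log_risk, event, time) {
  event <- as.logical(event)
  if (length(log_risk) != length(event) || length(event) != length(time)) {
    stop("log_risk, event and time must have equal length", call. = FALSE)
  }
  if (any(!is.finite(log_risk)) || any(!is.finite(time)) || any(time <= 0)) {
    stop("covariate must be finite and follow-up times positive",
         call. = FALSE)
  }
  n_events <- sum(event)
  if (n_events < 1L) {
    stop("no incident events: the Cox model cannot be fitted", call. = FALSE)
  }
  s <- stats::sd(log_risk)
  if (s == 0) {
    # constant covariate carries no information: beta = 0 by convention
    beta <- 0; se <- Inf; p <- 1; p_lrt <- 1
  } else {
    fit <- survival::coxph(survival::Surv(time, event) ~ log_risk,
                           ties = "efron")
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(stats::vcov(fit)[1, 1]))
    if (!is.finite(beta) || !is.finite(se)) {
      stop("Cox fit did not converge; check the data", call. = FALSE)
    }
    p <- 2 * stats::pnorm(-abs(beta / se))
    p_lrt <- stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]), df = 1,
                           lower.tail = FALSE)
  }
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  scale_to <- function(k) c(estimate = exp(beta * k),
                            ci_low = exp(ci[1] * k),
                            ci_high = exp(ci[2] * k))
  structure(
    list(beta = beta, se = se,
         hr_per_10fold = scale_to(log(10)),
         hr_per_sd = scale_to(s),
         p_value = p, p_value_lrt = p_lrt,
         n = length(log_risk), n_events = n_events, sd_log_risk = s),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f (%.2f-%.2f)", v["estimate"], v["ci_low"],
                             v["ci_high"])
  cat(sprintf("Cox PH: %d events / %d participants\n", x$n_events, x$n))
  cat(sprintf("  HR per 10-fold risk increase: %s\n", fmt(x$hr_per_10fold)))
  cat(sprintf("  HR per SD of log risk:        %s\n", fmt(x$hr_per_sd)))
  cat(sprintf("  Wald p = %.3g (LRT p = %.3g)\n", x$p_value, x$p_value_lrt))
  invisible(x)
}

#' Lower of the bilateral striatal binding values
#'
#' The lower of the left/right striatal binding ratios is taken as the
#' marker of dopaminergic depletion.
#'
#' @param left,right binding ratios.
#' @return elementwise minimum.
#' @export
select_binding <- function(left, right) {
  if (any(!is.finite(left)) || any(!is.finite(right))) {
    stop("binding values must be finite", call. = FALSE)
  }
  pmin(left, right)
}

#' Regression of striatal binding on log risk with bootstrap R² CI
#'
#' Ordinary least squares of the (lower bilateral) striatal binding ratio
#' on log risk odds. The R² confidence interval is a seed-deterministic
#' percentile bootstrap over participant resamples. An optional
#' quadratic-term F-test probes for non-linearity.
#'
#' @param log_odds numeric log risk per participant.
#' @param binding numeric binding ratio per participant (lower of the two
#'   sides, see [select_binding()]).
#' @param n_bootstrap bootstrap replicates (default 5000).
#' @param seed integer seed for the bootstrap resampling.
#' @param test_nonlinearity add a quadratic term and F-test it.
#' @return object of class `binding_regression`: `slope`
#'   (`c(estimate, ci_low, ci_high)`), `r_squared`, `r_squared_ci`,
#'   `p_value`, `nonlinearity_p`, `n`, `n_bootstrap`.
#' @export
binding_regression <- function(log_odds, binding, n_bootstrap = 5000L,
                               seed = 1L, test_nonlinearity = TRUE) {
  if (length(log_odds) != length(binding)) {
    stop("covariate and response lengths differ", call. = FALSE)
  }
  n <- length(log_odds)
  if (n < 3L) stop("need at least 3 participants", call. = FALSE)
  if (n_bootstrap < 1L) stop("need n_bootstrap >= 1", call. = FALSE)
  if (stats::sd(log_odds) == 0) {
    stop("log risk is constant: regression is degenerate", call. = FALSE)
  }
  df <- data.frame(x = log_odds, y = binding)
  fit <- stats::lm(y ~ x, data = df)
  sm <- summary(fit)
  slope_ci <- stats::confint(fit)["x", ]
  r2 <- sm$r.squared

  set.seed(seed)
  r2_boot <- vapply(seq_len(n_bootstrap), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- df[idx, ]
    if (stats::sd(d$x) == 0) return(NA_real_)
    summary(stats::lm(y ~ x, data = d))$r.squared
  }, numeric(1))
  r2_boot <- r2_boot[!is.na(r2_boot)]
  ci <- unname(stats::quantile(r2_boot, c(0.025, 0.975), type = 7))

  nl_p <- NA_real_
  if (test_nonlinearity && n >= 4L) {
    fit2 <- stats::lm(y ~ x + I(x^2), data = df)
    nl_p <- stats::anova(fit, fit2)[2, "Pr(>F)"]
  }
  structure(
    list(slope = c(estimate = unname(stats::coef(fit)["x"]),
                   ci_low = slope_ci[[1]], ci_high = slope_ci[[2]]),
         r_squared = r2,
         r_squared_ci = c(ci_low = ci[1], ci_high = ci[2]),
         p_value = sm$coefficients["x", "Pr(>|t|)"],
         nonlinearity_p = nl_p,
         n = n, n_bootstrap = length(r2_boot)),
    class = "binding_regression"
  )
}

#' @export
print.binding_regression <- function(x, ...) {
  cat(sprintf("Binding ~ log risk: n = %d\n", x$n))
  cat(sprintf("  slope %.3g (%.3g to %.3g), p = %.3g\n", x$slope["estimate"],
              x$slope["ci_low"], x$slope["ci_high"], x$p_value))
  cat(sprintf("  R^2 = %.3f [95%% CI %.3f-%.3f] (%d bootstrap replicates)\n",
              x$r_squared, x$r_squared_ci[1], x$r_squared_ci[2],
              x$n_bootstrap))
  if (is.finite(x$nonlinearity_p)) {
    cat(sprintf("  non-linearity F-test p = %.3g\n", x$nonlinearity_p))
  }
  invisible(x)
}

#' Choose the wave paired with DaT-SPECT imaging
#'
#' Imaging was acquired near years 2-3 of follow-up, so the risk estimate
#' paired with a participant's scan is taken from year 2 or year 3:
#' preferring the wave with observed (non-imputed) data, with ties broken
#' towards the earlier wave.
#'
#' @param waves data.frame of one participant's waves (with `survey_year`
#'   and `completed`).
#' @return the chosen survey year, or `NA` when neither wave exists.
#' @export
select_imaging_wave <- function(waves) {
  cand <- waves[waves$survey_year %in% c(2L, 3L), , drop = FALSE]
  if (!nrow(cand)) return(NA_integer_)
  if (!"completed" %in% names(cand)) cand$completed <- TRUE
  cand <- cand[order(-as.integer(cand$completed), cand$survey_year), ,
               drop = FALSE]
  as.integer(cand$survey_year[1L])
}
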