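#' Continuous age-based prior odds model
#'
#' The age-specific prior odds of PD follow
#' \deqn{odds(age) = 1 : (a + b e^{-c (age - 60)})}
#' i.e. the odds value is the reciprocal of the denominator. The default
#' coefficients (a = 22.098, b = 78.900, c = 0.14053 per year) were fitted
#' to the odds implied by the MDS prodromal criteria's 5-year age
#' categories, giving a smooth, strictly increasing risk with age. At the
#' reference age 60 the exponent vanishes, so the prior is 1:100.998; at
#' age 80 it is 1:27 after display rounding.
#'
#' @param a additive constant of the denominator.
#' @param b scale of the exponential term.
#' @param c decay rate per year of age (> 0).
#' @param age_ref reference age in years (where the exponent is zero).
#' @param valid_range ages (years) over which the equation is applied;
#'   outside it ages are clamped with a warning. The default [60, 90]
#'   covers a 60-80 year-old baseline cohort plus up to 7 years' follow-up.
#' @return object of class `age_prior_model`.
#' @export
age_prior_model <- function(a = 22.098, b = 78.900, c = 0.14053,
                            age_ref = 60, valid_range = c(60, 90)) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(valid_range) == 2L, valid_range[1] < valid_range[2])
  if (b <= 0 || c <= 0) {
    stop("'b' and 'c' must be positive for odds to increase with age",
         call. = FALSE)
  }
  m <- list(a = a, b = b, c = c, age_ref = age_ref,
            valid_range = as.numeric(valid_range))
  # denominator must stay positive over the valid range
  dmin <- .age_denominator(valid_range[2], m)
  if (!is.finite(dmin) || dmin <= 0) {
    stop("denominator non-positive on the valid range", call. = FALSE)
  }
  structure(m, class = "age_prior_model")
}

.age_denominator <- function(age, model) {
  model$a + model$b * exp(-model$c * (age - model$age_ref))
}

# unclamped evaluation, used internally and by the asymptote check
.age_prior_odds_unclamped <- function(age, model) {
  odds(1 / .age_denominator(age, model))
}

#' Age-based prior odds of PD
#'
#' Evaluate the continuous age-odds equation. Ages outside the model's
#' valid range are clamped to the nearest bound with a warning rather than
#' extrapolated, because the equation was fitted to age-category points
#' within that range.
#'
#' @param age age(s) in years.
#' @param model an [age_prior_model()].
#' @return an `odds` vector, strictly increasing in age.
#' @examples
#' format_odds(age_prior_odds(80))  # "1:27"
#' @export
age_prior_odds <- function(age, model = age_prior_model()) {
  if (!is.numeric(age) || any(!is.finite(age))) {
    stop("'age' must be finite numeric", call. = FALSE)
  }
  lo <- model$valid_range[1]; hi <- model$valid_range[2]
  if (any(age < lo) || any(age > hi)) {
    warning(sprintf("age outside [%g, %g] clamped to the nearest bound",
                    lo, hi), call. = FALSE)
    age <- pmin(pmax(age, lo), hi)
  }
  .age_prior_odds_unclamped(age, model)
}

#' Categorical (5-year-interval) age prior
#'
#' Piecewise-constant alternative prior used by the MDS-style variant:
#' prior odds per contiguous, half-open age interval \[lower, upper).
#' No default table ships with the package; interval odds must come from
#' user configuration.
#'
#' @param age age(s) in years.
#' @param table data.frame with columns `lower`, `upper` (years; contiguous,
#'   non-overlapping, half-open) and `odds` (positive odds values).
#' @return an `odds` vector. Ages at or beyond the last interval's upper
#'   bound take the last interval's value with a warning.
#' @export
categorical_age_prior <- function(age, table) {
  if (is.null(table) || !is.data.frame(table) || nrow(table) == 0L) {
    stop("categorical age-prior table is empty or missing", call. = FALSE)
  }
  stopifnot(all(c("lower", "upper", "odds") %in% names(table)))
  table <- table[order(table$lower), , drop = FALSE]
  if (any(table$upper <= table$lower) ||
      (nrow(table) > 1L &&
       any(abs(table$lower[-1L] - table$upper[-nrow(table)]) > 1e-9))) {
    stop("intervals must be contiguous, non-overlapping [lower, upper)",
         call. = FALSE)
  }
  if (any(table$odds <= 0)) stop("interval odds must be positive", call. = FALSE)
  idx <- findInterval(age, c(table$lower, table$upper[nrow(table)]),
                      rightmost.closed = FALSE)
  if (any(age >= table$upper[nrow(table)])) {
    warning("ages beyond the last interval take its value", call. = FALSE)
    idx[age >= table$upper[nrow(table)]] <- nrow(table)
  }
  if (any(idx < 1L)) {
    stop("age below the first interval of the categorical table",
         call. = FALSE)
  }
  odds(table$odds[idx])
}
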