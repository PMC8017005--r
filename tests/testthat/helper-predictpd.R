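# Shared fixtures and independent oracles for the test suite.

# one participant-wave with everything unknown unless overridden
make_wave <- function(...) {
  w <- list(participant_id = "P1", survey_year = 0L, age = 60, sex = "male")
  utils::modifyList(w, list(...))
}

# Cox partial log-likelihood written out from first principles (Efron ties),
# independent of survival::coxph. x is the covariate vector.
cox_pl <- function(beta, time, event, x) {
  r <- exp(beta * x)
  ll <- 0
  for (t in sort(unique(time[event]))) {
    d_idx <- which(event & time == t)
    at_risk <- which(time >= t)
    d <- length(d_idx)
    sum_risk <- sum(r[at_risk])
    sum_tied <- sum(r[d_idx])
    ll <- ll + sum(beta * x[d_idx])
    for (l in seq_len(d) - 1L) {
      ll <- ll - log(sum_risk - (l / d) * sum_tied)
    }
  }
  ll
}

# brute-force maximiser of the written-out partial likelihood
cox_brute <- function(time, event, x, lower = -10, upper = 10) {
  stats::optimize(function(b) cox_pl(b, time, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# quantile oracle: linear interpolation at position p*(n-1)+1 on the sorted
# sample, written out directly
quantile_oracle <- function(v, p) {
  s <- sort(v)
  h <- p * (length(s) - 1) + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# draw from a bivariate normal (independent of the package's sampler)
rbvn_oracle <- function(n, mean, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  a <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  matrix(stats::rnorm(2 * n), n, 2) %*% a +
    matrix(mean, n, 2, byrow = TRUE)
}

# small synthetic cohort shared across tests (fixed seed, modest n)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(simulation_config(n_participants = 400),
                                seed = 20240601)
    }
    cache
  }
})
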