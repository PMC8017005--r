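#' Odds in favour of disease
#'
#' Construct an `odds` object: the odds in favour of PD, stored as the
#' in-favour value \eqn{p/(1-p)}. The conventional screening notation
#' "1:N" corresponds to value \eqn{1/N}. Risk is carried on the odds scale
#' throughout the pipeline because multiplicative likelihood-ratio updates
#' are literal products on this scale, and odds are unbounded above so
#' large fold differences between high- and low-risk individuals remain
#' visible.
#'
#' @param value positive finite numeric vector, the odds in favour
#'   (\eqn{p/(1-p)}).
#' @return A numeric vector of class `odds`.
#' @examples
#' odds(1 / 100)          # "1:100"
#' odds_from_prob(0.5)    # even odds
#' @export
odds <- function(value) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
    stop("'value' must be positive and finite", call. = FALSE)
  }
  structure(as.numeric(value), class = "odds")
}

#' @rdname odds
#' @param p probability in (0, 1).
#' @export
odds_from_prob <- function(p) {
  if (any(p <= 0) || any(p >= 1)) stop("'p' must lie in (0, 1)", call. = FALSE)
  odds(p / (1 - p))
}

#' @rdname odds
#' @param x an `odds` object.
#' @export
prob_from_odds <- function(x) {
  v <- unclass(x)
  v / (1 + v)
}

#' @export
print.odds <- function(x, ...) {
  cat(format_odds(x), sep = "\n")
  invisible(x)
}

#' Render odds as "1:N" text
#'
#' Presentation-only rounding: the denominator \eqn{N = 1/value} is rounded
#' to the nearest integer when \eqn{N \ge 10}, otherwise to one decimal
#' place. All pipeline arithmetic stays at full double precision; this
#' formatting is applied only at display time.
#'
#' @param x an `odds` object (or positive numeric vector of odds values).
#' @return character vector like `"1:27"`.
#' @examples
#' format_odds(odds(1 / 26.84))  # "1:27"
#' @export
format_odds <- function(x) {
  v <- unclass(x)
  if (any(v <= 0)) stop("odds must be positive", call. = FALSE)
  n <- 1 / v
  ifelse(n >= 10,
         sprintf("1:%.0f", round(n)),
         sprintf("1:%.1f", round(n, 1)))
}

#' Parse "1:N" odds text
#'
#' Inverse of [format_odds()] up to its display rounding.
#'
#' @param text character vector like `"1:27"`.
#' @return an `odds` object.
#' @export
parse_odds <- function(text) {
  m <- regmatches(text, regexec("^1:([0-9.]+)$", text))
  n <- vapply(m, function(g) {
    if (length(g) != 2L) return(NA_real_)
    as.numeric(g[2L])
  }, numeric(1))
  if (any(is.na(n)) || any(n <= 0)) {
    stop("cannot parse odds text; expected \"1:N\"", call. = FALSE)
  }
  odds(1 / n)
}

#' Likelihood-ratio pair for one risk factor
#'
#' A positive/negative likelihood-ratio pair (LR+, LR-). `source` records
#' provenance: taken directly from the literature, or converted from an
#' odds ratio and an exposure prevalence via [or_to_lr()]. Factors for
#' which no prevalence data exist and hence no LR- could be derived
#' (pesticide exposure, first-degree relative with PD) carry `lr_neg = 1`
#' with `no_lr_neg = TRUE`, so known absence leaves the risk estimate
#' unchanged.
#'
#' @param lr_pos positive likelihood ratio (> 0).
#' @param lr_neg negative likelihood ratio (> 0).
#' @param source `"literature"` or `"converted"`.
#' @param or_value optional odds ratio the pair was converted from.
#' @param prevalence optional exposure prevalence in (0, 1).
#' @param no_lr_neg logical; `TRUE` when no LR- could be calculated and the
#'   unit value is a deliberate no-information placeholder.
#' @return object of class `lr_pair`.
#' @export
lr_pair <- function(lr_pos, lr_neg, source = c("literature", "converted"),
                    or_value = NULL, prevalence = NULL, no_lr_neg = FALSE) {
  source <- match.arg(source)
  if (!is.finite(lr_pos) || lr_pos <= 0) {
    stop("'lr_pos' must be positive and finite", call. = FALSE)
  }
  if (!is.finite(lr_neg) || lr_neg <= 0) {
    stop("'lr_neg' must be positive and finite", call. = FALSE)
  }
  structure(
    list(lr_pos = lr_pos, lr_neg = lr_neg, source = source,
         or_value = or_value, prevalence = prevalence,
         no_lr_neg = isTRUE(no_lr_neg)),
    class = "lr_pair"
  )
}

#' @export
print.lr_pair <- function(x, ...) {
  cat(sprintf("LR+ = %.4g, LR- = %.4g (%s%s)\n", x$lr_pos, x$lr_neg, x$source,
              if (x$no_lr_neg) "; no LR- available, unit placeholder" else ""))
  invisible(x)
}

#' Convert an odds ratio to a likelihood-ratio pair
#'
#' Given a factor's odds ratio for association with PD and its prevalence
#' in the source population, derive the positive and negative likelihood
#' ratios:
#' \deqn{LR+ = OR / ((1 - prev) + prev \cdot OR)}
#' \deqn{LR- = 1 / ((1 - prev) + prev \cdot OR)}
#' Two identities follow immediately and are relied on as invariants:
#' \eqn{LR+/LR- = OR} and \eqn{prev \cdot LR+ + (1 - prev) \cdot LR- = 1}
#' (the prevalence-weighted mean of the two likelihood ratios is unity).
#'
#' @param or_value odds ratio, > 0.
#' @param prevalence exposure prevalence in (0, 1).
#' @return an [lr_pair()] with `source = "converted"`.
#' @examples
#' or_to_lr(1.58, 0.03)  # head injury: LR+ 1.55, LR- 0.98
#' or_to_lr(0.83, 0.80)  # NSAID use:  LR+ 0.96, LR- 1.16
#' @export
or_to_lr <- function(or_value, prevalence) {
  if (!is.numeric(or_value) || !is.finite(or_value) || or_value <= 0) {
    stop("'or_value' must be a positive finite number", call. = FALSE)
  }
  if (!is.numeric(prevalence) || !is.finite(prevalence) ||
      prevalence <= 0 || prevalence >= 1) {
    stop("'prevalence' must lie strictly in (0, 1)", call. = FALSE)
  }
  denom <- (1 - prevalence) + prevalence * or_value
  lr_pair(lr_pos = or_value / denom, lr_neg = 1 / denom,
          source = "converted", or_value = or_value, prevalence = prevalence)
}

#' Combine prior odds with likelihood-ratio multipliers
#'
#' Multiplicative (naive-Bayes) combination: posterior odds = prior odds
#' times the product of per-factor likelihood ratios, assuming independence
#' of the factors. An empty factor sequence returns the prior unchanged.
#'
#' @param prior an `odds` object (scalar).
#' @param factors numeric vector of positive multipliers (possibly empty).
#' @return an `odds` object.
#' @examples
#' combine_lrs(odds(1 / 100), c(2.5, 0.8))  # 1:50
#' @export
combine_lrs <- function(prior, factors = numeric()) {
  if (!inherits(prior, "odds")) prior <- odds(prior)
  if (length(factors) &&
      (!is.numeric(factors) || any(!is.finite(factors)) || any(factors <= 0))) {
    stop("all likelihood-ratio factors must be positive and finite",
         call. = FALSE)
  }
  odds(unclass(prior) * prod(factors))
}
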