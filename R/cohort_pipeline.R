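# Survey-year domain. Year 5 is structurally absent (no data were collected
# in the 5th follow-up year), so imputation never creates a year-5 record.
.SURVEY_YEARS <- c(0L, 1L, 2L, 3L, 4L, 6L)

.odour_cols <- function(df) grep("^odour_", names(df), value = TRUE)

#' Impute missing survey waves for one participant
#'
#' Longitudinal carry-forward imputation:
#' \itemize{
#'   \item Gaps strictly between observed waves are filled by copying the
#'     preceding wave's exposures with age incremented one year per survey
#'     year. Nothing is imputed after the last observed wave (no certainty
#'     of continued participation), and no year-5 record is ever created.
#'   \item Smell tests are administered only at baseline and year 3:
#'     baseline odour responses are applied to years 1 and 2, year-3
#'     responses to years 4 and 6. Waves whose rule source is missing get
#'     no smell data (the smell multiplier is then 1).
#'   \item Pesticide exposure is collected from year 3 onwards; the year-3
#'     status is back-filled to all earlier waves.
#' }
#' Imputed rows carry `completed = FALSE` and are excluded from completed
#' survey counts. The operation is idempotent and never alters observed
#' waves' observed fields.
#'
#' @param waves data.frame of one participant's observed waves, ordered by
#'   `survey_year` (a subset of 0,1,2,3,4,6).
#' @return data.frame of observed plus imputed waves, ordered by year.
#' @export
impute_waves <- function(waves) {
  stopifnot(is.data.frame(waves), nrow(waves) >= 1L)
  if (!"survey_year" %in% names(waves)) stop("'survey_year' column required",
                                             call. = FALSE)
  yr <- as.integer(waves$survey_year)
  if (anyDuplicated(yr)) stop("duplicate survey years", call. = FALSE)
  if (any(!yr %in% .SURVEY_YEARS)) {
    stop("survey years must lie in {0,1,2,3,4,6} (no data exist for year 5)",
         call. = FALSE)
  }
  waves <- waves[order(yr), , drop = FALSE]
  yr <- sort(yr)
  if (!"completed" %in% names(waves)) waves$completed <- TRUE

  observed_years <- yr[waves$completed]
  if (!length(observed_years)) observed_years <- yr
  last_obs <- max(observed_years)
  # target years: everything in the domain up to the last observed wave
  target <- .SURVEY_YEARS[.SURVEY_YEARS >= min(yr) & .SURVEY_YEARS <= last_obs]

  out <- waves
  for (y in setdiff(target, yr)) {
    prev_idx <- max(which(out$survey_year < y))
    row <- out[prev_idx, , drop = FALSE]
    gap <- y - row$survey_year
    row$survey_year <- y
    row$age <- row$age + gap   # one year older per survey year
    row$completed <- FALSE
    out <- rbind(out, row)
    out <- out[order(out$survey_year), , drop = FALSE]
  }

  oc <- .odour_cols(out)
  if (length(oc)) {
    src_for <- function(y) switch(as.character(y),
                                  "1" = 0L, "2" = 0L, "4" = 3L, "6" = 3L,
                                  NA_integer_)
    for (i in seq_len(nrow(out))) {
      s <- src_for(out$survey_year[i])
      if (is.na(s)) next   # years 0 and 3 keep their own test results
      j <- which(out$survey_year == s & out$completed)
      out[i, oc] <- if (length(j) == 1L && !all(is.na(out[j, oc]))) {
        out[j, oc]
      } else NA_real_
    }
  }

  if ("pesticides" %in% names(out)) {
    j3 <- which(out$survey_year >= 3L)
    early <- which(out$survey_year < 3L)
    if (length(j3) && length(early)) {
      y3 <- out$pesticides[j3[1L]]
      if (!is.na(y3) && y3 != "U") out$pesticides[early] <- y3
    }
  }

  rownames(out) <- NULL
  out
}

#' Impute missing waves across a cohort
#'
#' Applies [impute_waves()] per participant.
#'
#' @param cohort data.frame of observed participant-waves.
#' @return data.frame of observed plus imputed waves.
#' @export
impute_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), "participant_id" %in% names(cohort))
  pieces <- lapply(split(cohort, cohort$participant_id), impute_waves)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$participant_id, out$survey_year), , drop = FALSE]
}

#' Centile summary of a risk distribution
#'
#' Selected centiles of the odds for one survey year, plus the 90th/10th
#' and 75th/25th centile fold differences. Quantiles use linear
#' interpolation of order statistics at position p(n-1)+1 (type 7), fixed
#' so that fold differences are reproducible bit-for-bit. Extreme-tail
#' fold differences (min/max, 1st/99th) are deliberately not computed:
#' with continuous markers in the score they are dominated by outliers.
#'
#' @param odds_values positive finite numeric odds (n >= 2).
#' @param centiles centiles to report, in percent.
#' @return one-row data.frame: `n`, one `cent_*` column per centile,
#'   `fold_90_10`, `fold_75_25`.
#' @export
summarize_distribution <- function(odds_values,
                                   centiles = c(1, 2.5, 10, 25, 50, 75, 90,
                                                95, 97.5, 99)) {
  v <- unclass(odds_values)
  if (!length(v)) stop("no odds supplied", call. = FALSE)
  if (length(v) < 2L || any(!is.finite(v)) || any(v <= 0)) {
    stop("need n >= 2 finite positive odds", call. = FALSE)
  }
  q <- stats::quantile(v, probs = centiles / 100, type = 7, names = FALSE)
  qf <- stats::quantile(v, probs = c(0.10, 0.25, 0.75, 0.90), type = 7,
                        names = FALSE)
  out <- data.frame(n = length(v))
  for (i in seq_along(centiles)) {
    out[[paste0("cent_", gsub("\\.", "_", centiles[i]))]] <- q[i]
  }
  out$fold_90_10 <- qf[4] / qf[1]
  out$fold_75_25 <- qf[3] / qf[2]
  out
}

#' Centile summaries per survey year
#'
#' @param scores data.frame with `survey_year` and `odds` columns (e.g. the
#'   output of [score_cohort()]).
#' @param centiles centiles in percent.
#' @return data.frame, one row per survey year.
#' @export
summarize_cohort <- function(scores, centiles = c(1, 2.5, 10, 25, 50, 75, 90,
                                                  95, 97.5, 99)) {
  stopifnot(all(c("survey_year", "odds") %in% names(scores)))
  rows <- lapply(split(scores$odds, scores$survey_year), function(v) {
    summarize_distribution(v, centiles)
  })
  out <- do.call(rbind, rows)
  out <- cbind(survey_year = as.integer(names(rows)), out)
  rownames(out) <- NULL
  out
}

#' Log-scale histogram of risk odds
#'
#' Bins odds on a log10-uniform grid aligned to decade boundaries
#' (`bins_per_decade` bins per factor of 10). The total count is preserved.
#'
#' @param odds_values positive numeric odds.
#' @param bins_per_decade integer >= 1 (default 5).
#' @return data.frame with `bin_lower`, `bin_upper` (odds scale),
#'   `log10_lower`, `log10_upper`, `count`.
#' @export
histogram_export <- function(odds_values, bins_per_decade = 5L) {
  v <- unclass(odds_values)
  if (!length(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop("odds must be positive and finite", call. = FALSE)
  }
  stopifnot(bins_per_decade >= 1L)
  l <- log10(v)
  # snap-to-grid guard so exact decade boundaries stay on decade bins
  eps <- 1e-9
  lo <- floor(min(l) * bins_per_decade + eps) / bins_per_decade
  hi <- ceiling(max(l) * bins_per_decade - eps) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  breaks <- seq(lo, hi, by = 1 / bins_per_decade)
  idx <- findInterval(l, breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(breaks) - 1L)  # boundary jitter guard
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(
    bin_lower = 10^breaks[-length(breaks)],
    bin_upper = 10^breaks[-1L],
    log10_lower = breaks[-length(breaks)],
    log10_upper = breaks[-1L],
    count = counts
  )
}

#' Read / write a cohort CSV
#'
#' One row per participant-wave. Exposure columns use P/A/U codes, odour
#' columns are 0/1, `ks_raw`/`at_raw` numeric, `completed` logical.
#'
#' @param path file path.
#' @return `read_cohort` returns a data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("completed" %in% names(df)) df$completed <- as.logical(df$completed)
  df
}

#' @rdname read_cohort
#' @param cohort data.frame of participant-waves.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
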