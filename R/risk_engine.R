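# Canonical factor sets per algorithm variant. The enhanced catalogue adds
# head injury and the NSAID/CCB/beta-blocker/alcohol medication-exposure
# factors, which the MDS catalogue does not consider; the basic catalogue
# predates RBD/diabetes/pesticides/never-smoked.
.FACTORS_ENHANCED <- c("coffee", "current_smoker", "former_smoker",
                       "never_smoked", "relative_pd", "constipation",
                       "erectile_dysfunction", "depression_anxiety",
                       "pesticides", "diabetes", "head_injury", "nsaid",
                       "ccb", "beta_blocker", "alcohol", "rbd")
.FACTORS_BASIC <- c("coffee", "current_smoker", "former_smoker",
                    "relative_pd", "constipation", "erectile_dysfunction",
                    "depression_anxiety", "head_injury", "nsaid", "ccb",
                    "beta_blocker", "alcohol")
.FACTORS_MDS <- c("coffee", "current_smoker", "former_smoker",
                  "never_smoked", "relative_pd", "constipation",
                  "erectile_dysfunction", "depression_anxiety",
                  "pesticides", "diabetes", "rbd")
.SMOKING_FACTORS <- c("current_smoker", "former_smoker", "never_smoked")

#' Shipped factor tables
#'
#' Loads the versioned JSON factor catalogue bundled with the package:
#' likelihood-ratio pairs per risk factor for the enhanced and MDS-style
#' variants, odds ratios for the basic variant, and the dichotomous
#' motor/olfactory marker LRs used by the MDS-style variant. Factor tables
#' are data, not code, so future evidence updates replace the JSON only.
#'
#' @param path path to a factor-table JSON; defaults to the shipped file.
#' @return nested list as stored in the JSON.
#' @export
default_factor_tables <- function(path = system.file("extdata",
                                                     "factor_tables.json",
                                                     package = "predictpd")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("factor-table JSON not found", call. = FALSE)
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Algorithm variant definition
#'
#' Assembles one of the three risk-algorithm variants from a factor-table
#' catalogue:
#' \describe{
#'   \item{basic}{odds-ratio based; an OR is multiplied in only when the
#'     factor is recorded present (female sex multiplies 0.67); the
#'     objective markers are excluded.}
#'   \item{enhanced16 / enhanced6}{likelihood-ratio based; LR+ when
#'     present, LR- when absent, 1 when unknown; continuous smell
#'     (16- or 6-odour logistic score) and tapping (bivariate Gaussian
#'     density ratio) markers; sex LR 1.2 (male) / 0.8 (female).}
#'   \item{mds}{likelihood-ratio based with the MDS catalogue subset;
#'     smell and motor impairment enter as dichotomised markers
#'     (LR+ 4.0 / LR- 0.43 and LR+ 3.5 / LR- 0.60).}
#' }
#'
#' @param name one of `"basic"`, `"enhanced16"`, `"enhanced6"`, `"mds"`.
#' @param tables factor-table catalogue, see [default_factor_tables()].
#' @param age_mode `"equation"` (continuous age-odds equation) or
#'   `"categorical"` (5-year-interval table, MDS style; requires an age
#'   table in the model bundle). Defaults to `"categorical"` for `mds`
#'   and `"equation"` otherwise.
#' @return object of class `algorithm_variant`.
#' @export
algorithm_variant <- function(name = c("basic", "enhanced16", "enhanced6",
                                       "mds"),
                              tables = default_factor_tables(),
                              age_mode = NULL) {
  name <- match.arg(name)
  key <- switch(name, basic = "basic", mds = "mds", "enhanced")
  tab <- tables[[key]]
  if (is.null(tab)) {
    stop(sprintf("factor tables have no '%s' entry", key), call. = FALSE)
  }
  required <- switch(name,
                     basic = .FACTORS_BASIC,
                     mds = .FACTORS_MDS,
                     .FACTORS_ENHANCED)
  scale <- if (name == "basic") "or" else "lr"
  missing_f <- setdiff(required, names(tab$factors))
  bad <- vapply(tab$factors[intersect(required, names(tab$factors))],
                function(f) {
                  if (scale == "or") is.null(f$or) || f$or <= 0
                  else is.null(f$lr_pos) || f$lr_pos <= 0 ||
                    (!is.null(f$lr_neg) && f$lr_neg <= 0)
                }, logical(1))
  if (length(missing_f) || any(bad)) {
    stop(sprintf("variant '%s' table incomplete; missing or invalid: [%s]",
                 name,
                 paste(c(missing_f, names(bad)[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(tab$sex$male) || is.null(tab$sex$female)) {
    stop("variant table lacks sex multipliers", call. = FALSE)
  }
  marker_mode <- switch(name, basic = "excluded", mds = "dichotomous",
                        "continuous")
  if (marker_mode == "dichotomous" &&
      (is.null(tab$markers$motor$lr_pos) || is.null(tab$markers$smell$lr_pos))) {
    stop("mds variant table lacks dichotomous marker LRs", call. = FALSE)
  }
  if (is.null(age_mode)) {
    age_mode <- if (name == "mds") "categorical" else "equation"
  }
  age_mode <- match.arg(age_mode, c("equation", "categorical"))
  structure(
    list(name = name, scale = scale,
         sex = c(male = tab$sex$male, female = tab$sex$female),
         factors = tab$factors[required],
         markers = tab$markers,
         marker_mode = marker_mode,
         smell_panel = switch(name, enhanced16 = "smell16",
                              enhanced6 = "smell6", NULL),
         age_mode = age_mode,
         version = tables$version),
    class = "algorithm_variant"
  )
}

#' @export
print.algorithm_variant <- function(x, ...) {
  cat(sprintf("PREDICT-PD algorithm variant '%s' (%s scale, markers %s, age %s)\n",
              x$name, x$scale, x$marker_mode, x$age_mode))
  cat(sprintf("  %d dichotomous factors; table version %s\n",
              length(x$factors), x$version %||% "unversioned"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default marker-model bundle
#'
#' Loads the shipped marker parameter set (MoM medians, case/control
#' bivariate Gaussians for tapping, 16- and 6-odour logistic smell models,
#' dichotomisation thresholds) plus the continuous age-prior model. The
#' shipped smell/tapping parameters are a synthetic fixture aligned with
#' the package's cohort generator, not the published case-control fits;
#' studies scoring real cohorts must supply their own via
#' [read_marker_models()].
#'
#' @param path path to a marker-model JSON; defaults to the shipped
#'   synthetic fixture.
#' @return list with components `mom`, `tapping`, `smell16`, `smell6`,
#'   `thresholds`, `odour_error_control`, `odour_error_case`, `age`,
#'   `age_table`.
#' @export
default_marker_models <- function(path = system.file(
  "extdata", "marker_models_synthetic.json", package = "predictpd")) {
  read_marker_models(path)
}

#' @rdname default_marker_models
#' @export
read_marker_models <- function(path) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("marker-model file not found", call. = FALSE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  smell <- function(s) logistic_smell_model(
    intercept = s$intercept,
    coefficients = unlist(s$coefficients),
    training_prevalence = s$training_prevalence)
  list(
    mom = mom_transform(j$mom$median_ks, j$mom$median_at),
    tapping = bivariate_lr_model(j$tapping$mean_case, j$tapping$mean_control,
                                 j$tapping$cov_case, j$tapping$cov_control),
    smell16 = smell(j$smell16),
    smell6 = smell(j$smell6),
    thresholds = as.list(j$thresholds),
    odour_error_control = unlist(j$odour_error_control),
    odour_error_case = unlist(j$odour_error_case),
    age = age_prior_model(),
    age_table = NULL
  )
}

# --- exposure-profile validation -------------------------------------------

.check_profile <- function(cohort) {
  if (!all(c("age", "sex") %in% names(cohort)) ||
      any(is.na(cohort$age)) || any(is.na(cohort$sex))) {
    stop("every wave needs a valid age and sex", call. = FALSE)
  }
  if (!all(cohort$sex %in% c("male", "female"))) {
    stop("sex must be \"male\" or \"female\"; unknown sex is not allowed",
         call. = FALSE)
  }
  smk <- intersect(.SMOKING_FACTORS, names(cohort))
  if (length(smk) == 3L) {
    st <- cbind(cohort$current_smoker, cohort$former_smoker,
                cohort$never_smoked)
    st[is.na(st)] <- "U"
    known <- rowSums(st != "U") > 0
    n_present <- rowSums(st == "P")
    if (any(known & n_present != 1L)) {
      stop("smoking states must be mutually exclusive: exactly one present ",
           "when known, or all unknown", call. = FALSE)
    }
  }
  if ("erectile_dysfunction" %in% names(cohort)) {
    ed <- cohort$erectile_dysfunction
    ed[is.na(ed)] <- "U"
    if (any(cohort$sex == "female" & ed == "P")) {
      stop("erectile dysfunction must be unknown or absent for females",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Column of P/A/U statuses for a factor; absent column = all unknown.
.status_col <- function(cohort, factor) {
  if (factor %in% names(cohort)) {
    s <- as.character(cohort[[factor]])
    s[is.na(s)] <- "U"
    s
  } else rep("U", nrow(cohort))
}

# odour response matrix (1 = correct) for the panel, NA rows = no test
.smell_matrix <- function(cohort, panel_items) {
  cols <- paste0("odour_", panel_items)
  out <- matrix(NA_real_, nrow(cohort), length(panel_items),
                dimnames = list(NULL, panel_items))
  for (i in seq_along(cols)) {
    if (cols[i] %in% names(cohort)) out[, i] <- cohort[[cols[i]]]
  }
  out
}

# --- vectorised scoring core ------------------------------------------------

# Returns a list(prior = numeric n, multipliers = named list of numeric n).
.risk_components <- function(cohort, variant, models) {
  n <- nrow(cohort)
  .check_profile(cohort)

  prior <- if (variant$age_mode == "categorical") {
    if (is.null(models$age_table)) {
      stop("variant requests a categorical age prior but no age table is ",
           "configured; supply models$age_table or age_mode = \"equation\"",
           call. = FALSE)
    }
    unclass(categorical_age_prior(cohort$age, models$age_table))
  } else {
    unclass(age_prior_odds(cohort$age, models$age))
  }

  mult <- list()
  mult$sex <- unname(variant$sex[cohort$sex])

  for (f in names(variant$factors)) {
    spec_f <- variant$factors[[f]]
    status <- .status_col(cohort, f)
    if (f == "erectile_dysfunction") status[cohort$sex == "female"] <- "U"
    mult[[f]] <- if (variant$scale == "or") {
      # basic algorithm: OR applied only when recorded present
      ifelse(status == "P", spec_f$or, 1)
    } else {
      status_multiplier(status, lr_pos = spec_f$lr_pos,
                        lr_neg = spec_f$lr_neg %||% 1)
    }
  }

  if (variant$marker_mode == "continuous") {
    sm_model <- models[[variant$smell_panel]]
    resp <- .smell_matrix(cohort, names(sm_model$coefficients))
    complete <- rowSums(is.na(resp)) == 0L
    sm <- rep(1, n)
    if (any(complete)) {
      sm[complete] <- smell_lr(resp[complete, , drop = FALSE], sm_model)
    }
    mult$smell <- sm

    tap <- rep(1, n)
    has_tap <- !is.na(cohort$ks_raw %||% rep(NA, n)) &
      !is.na(cohort$at_raw %||% rep(NA, n))
    if (any(has_tap)) {
      dm <- to_delta_mom(cohort$ks_raw[has_tap], cohort$at_raw[has_tap],
                         models$mom)
      tap[has_tap] <- tapping_lr(dm, models$tapping)
    }
    mult$tapping <- tap
  } else if (variant$marker_mode == "dichotomous") {
    thr <- models$thresholds
    if (is.null(thr)) {
      stop("dichotomisation thresholds required for the MDS-style variant",
           call. = FALSE)
    }
    # motor status
    has_tap <- !is.na(cohort$ks_raw %||% rep(NA, n)) &
      !is.na(cohort$at_raw %||% rep(NA, n))
    motor <- rep("U", n)
    if (any(has_tap)) {
      dm <- to_delta_mom(cohort$ks_raw[has_tap], cohort$at_raw[has_tap],
                         models$mom)
      motor[has_tap] <- ifelse(dm[, 1] < thr$motor_ks |
                                 dm[, 2] > thr$motor_at, "P", "A")
    }
    mult$motor <- status_multiplier(motor,
                                    lr_pos = variant$markers$motor$lr_pos,
                                    lr_neg = variant$markers$motor$lr_neg)
    # olfactory status from the 16-odour panel
    resp <- .smell_matrix(cohort, names(models$smell16$coefficients))
    complete <- rowSums(is.na(resp)) == 0L
    smell <- rep("U", n)
    n_err <- rowSums(1 - resp)
    smell[complete] <- ifelse(n_err[complete] > thr$smell_errors, "P", "A")
    mult$smell <- status_multiplier(smell,
                                    lr_pos = variant$markers$smell$lr_pos,
                                    lr_neg = variant$markers$smell$lr_neg)
  }

  list(prior = prior, multipliers = mult)
}

#' Score a cohort of participant-waves
#'
#' Vectorised risk computation: one combined odds per row of the cohort
#' table under the chosen algorithm variant. Missing measurements
#' contribute the no-information multiplier 1; unknown dichotomous factors
#' likewise.
#'
#' @param cohort data.frame, one row per participant-wave (see the column
#'   dictionary in the package vignette): `participant_id`, `survey_year`,
#'   `age`, `sex`, P/A/U exposure columns, `rbd`, `odour_*` 0/1 columns,
#'   `ks_raw`, `at_raw`.
#' @param variant an [algorithm_variant()].
#' @param models marker/config bundle, see [default_marker_models()].
#' @param breakdown if `TRUE`, per-factor multiplier columns are appended.
#' @return data.frame with `participant_id`, `survey_year`, `odds`,
#'   `log_odds`, `odds_text` (and multiplier columns when requested).
#' @export
score_cohort <- function(cohort, variant, models = default_marker_models(),
                         breakdown = FALSE) {
  stopifnot(inherits(variant, "algorithm_variant"), is.data.frame(cohort))
  comp <- .risk_components(cohort, variant, models)
  o <- comp$prior
  for (m in comp$multipliers) o <- o * m
  out <- data.frame(
    participant_id = cohort$participant_id %||% seq_len(nrow(cohort)),
    survey_year = cohort$survey_year %||% rep(0L, nrow(cohort)),
    variant = variant$name,
    odds = o,
    log_odds = log(o),
    odds_text = format_odds(odds(o)),
    stringsAsFactors = FALSE
  )
  if (breakdown) {
    out$prior <- comp$prior
    for (nm in names(comp$multipliers)) {
      out[[paste0("lr_", nm)]] <- comp$multipliers[[nm]]
    }
  }
  out
}

#' Risk estimate for a single participant-wave
#'
#' Computes the combined odds together with an auditable multiplicative
#' breakdown: the age prior and every factor/marker multiplier applied, in
#' order, whose product reconstructs the odds exactly.
#'
#' @param wave a one-row data.frame or named list for one participant-wave.
#' @param variant an [algorithm_variant()].
#' @param models marker/config bundle.
#' @return object of class `risk_estimate` with fields `odds`, `variant`,
#'   `breakdown` (named numeric, first element the age prior), `wave`.
#' @examples
#' w <- list(age = 60, sex = "male")
#' compute_risk(w, algorithm_variant("enhanced16"))
#' @export
compute_risk <- function(wave, variant, models = default_marker_models()) {
  if (!is.data.frame(wave)) wave <- as.data.frame(wave, stringsAsFactors = FALSE)
  stopifnot(nrow(wave) == 1L)
  comp <- .risk_components(wave, variant, models)
  mult <- vapply(comp$multipliers, `[`, numeric(1), 1L)
  structure(
    list(odds = odds(comp$prior * prod(mult)),
         variant = variant$name,
         breakdown = c(prior = comp$prior, mult),
         wave = wave$survey_year %||% 0L),
    class = "risk_estimate"
  )
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("PD risk (%s, survey year %s): %s (odds %.6g)\n",
              x$variant, x$wave, format_odds(x$odds), unclass(x$odds)))
  nontrivial <- x$breakdown[abs(x$breakdown - 1) > 1e-12 |
                              names(x$breakdown) == "prior"]
  cat("  breakdown:",
      paste(sprintf("%s=%.4g", names(nontrivial), nontrivial),
            collapse = ", "), "\n")
  invisible(x)
}

#' Risk trajectory across survey waves
#'
#' One risk estimate per available (observed or imputed) wave of a single
#' participant, ordered by survey year. Imputation of missing intermediate
#' waves is the cohort pipeline's job ([impute_waves()]); no estimate is
#' produced after the participant's last recorded wave.
#'
#' @param waves data.frame of one participant's waves.
#' @param variant an [algorithm_variant()].
#' @param models marker/config bundle.
#' @return list of `risk_estimate`, one per wave.
#' @export
risk_trajectory <- function(waves, variant, models = default_marker_models()) {
  stopifnot(is.data.frame(waves), nrow(waves) >= 1L)
  yr <- waves$survey_year
  if (is.null(yr) || is.unsorted(yr, strictly = TRUE)) {
    stop("waves must be ordered by survey year without duplicates",
         call. = FALSE)
  }
  lapply(seq_len(nrow(waves)), function(i) {
    compute_risk(waves[i, , drop = FALSE], variant, models)
  })
}
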