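#' Read / write a run configuration
#'
#' Run configurations are plain JSON (or YAML, if the `yaml` package is
#' available) documents holding the variant selection, optional paths to a
#' factor-table JSON and marker-model parameter file, a seed and a
#' verbosity flag. Referenced files are checked for existence up front,
#' before any computation.
#'
#' @param path config file path (`.json`, `.yaml` or `.yml`).
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a run-config list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  config <- as.list(config)
  config$variant <- config$variant %||% "enhanced16"
  if (!config$variant %in% c("basic", "enhanced16", "enhanced6", "mds")) {
    stop("config field 'variant' must be one of basic, enhanced16, ",
         "enhanced6, mds (got '", config$variant, "')", call. = FALSE)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$verbose <- isTRUE(config$verbose)
  for (f in c("factor_tables", "marker_models")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("config field '", f, "' points to a missing file: ", config[[f]],
           call. = FALSE)
    }
  }
  structure(config, class = "run_config")
}

.load_bundle <- function(config) {
  tables <- if (is.null(config$factor_tables)) default_factor_tables()
  else default_factor_tables(config$factor_tables)
  models <- if (is.null(config$marker_models)) default_marker_models()
  else read_marker_models(config$marker_models)
  # the MDS-style variant falls back to the continuous age equation when no
  # categorical interval table is configured
  age_mode <- if (config$variant == "mds" && is.null(models$age_table)) {
    "equation"
  } else NULL
  list(variant = algorithm_variant(config$variant, tables = tables,
                                   age_mode = age_mode),
       models = models)
}

.log_run <- function(config, inputs) {
  if (!isTRUE(config$verbose)) return(invisible(NULL))
  hashes <- vapply(inputs[file.exists(unlist(inputs))],
                   function(p) unname(tools::md5sum(p)), character(1))
  message(sprintf("[predictpd] variant=%s seed=%d", config$variant,
                  config$seed))
  for (nm in names(hashes)) {
    message(sprintf("[predictpd] input %s md5=%s", nm, hashes[[nm]]))
  }
}

#' Run a pipeline command
#'
#' Programmatic equivalent of the command-line interface: chains the
#' package's stages deterministically given a seed.
#' \describe{
#'   \item{simulate}{generate a synthetic cohort; writes waves and
#'     outcomes CSVs.}
#'   \item{score}{impute missing waves of a cohort CSV and score every
#'     wave under the configured variant; writes a per-wave odds CSV and
#'     reports the number of imputed waves.}
#'   \item{summarize}{score, then write the per-year centile table and
#'     per-year log-scale histogram CSVs.}
#'   \item{validate}{Cox fit of incident PD on baseline log risk (and,
#'     when a binding CSV is supplied, the binding regression); writes a
#'     JSON results file.}
#' }
#'
#' @param command one of `"score"`, `"summarize"`, `"simulate"`,
#'   `"validate"`.
#' @param config a `run_config` (see [read_run_config()]) plus
#'   command-specific fields: `input` (cohort CSV), `outcomes` (outcomes
#'   CSV), `binding` (optional binding CSV with columns `participant_id`,
#'   `left`, `right`), `output` (output file or directory), `n` (simulate).
#' @return invisibly, a list of written artifact paths and key results.
#' @export
run_pipeline <- function(command = c("score", "summarize", "simulate",
                                     "validate"),
                         config) {
  command <- match.arg(command)
  config <- validate_run_config(config)
  out_dir <- config$output %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  bundle <- .load_bundle(config)
  .log_run(config, list(input = config$input %||% "",
                        outcomes = config$outcomes %||% ""))

  if (command == "simulate") {
    sc <- simulation_config(n_participants = config$n %||% 1323,
                            models = bundle$models)
    sim <- simulate_cohort(sc, seed = config$seed)
    paths <- file.path(out_dir, c("cohort.csv", "outcomes.csv"))
    write_cohort(sim$waves, paths[1])
    utils::write.csv(sim$outcomes, paths[2], row.names = FALSE)
    return(invisible(list(paths = paths)))
  }

  if (is.null(config$input)) stop("config field 'input' (cohort CSV) required",
                                  call. = FALSE)
  cohort <- read_cohort(config$input)
  imputed <- impute_cohort(cohort)
  n_imputed <- sum(!imputed$completed)
  if (isTRUE(config$verbose)) {
    message(sprintf("[predictpd] %d waves imputed", n_imputed))
  }
  scores <- score_cohort(imputed, bundle$variant, bundle$models,
                         breakdown = isTRUE(config$breakdown))
  scores$completed <- imputed$completed

  if (command == "score") {
    p <- file.path(out_dir, sprintf("scores_%s.csv", config$variant))
    utils::write.csv(scores, p, row.names = FALSE)
    return(invisible(list(paths = p, n_imputed = n_imputed)))
  }

  if (command == "summarize") {
    cent <- summarize_cohort(scores)
    p1 <- file.path(out_dir, sprintf("centiles_%s.csv", config$variant))
    utils::write.csv(cent, p1, row.names = FALSE)
    paths <- p1
    for (y in unique(scores$survey_year)) {
      h <- histogram_export(scores$odds[scores$survey_year == y])
      p <- file.path(out_dir, sprintf("hist_%s_year%d.csv", config$variant, y))
      utils::write.csv(h, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    return(invisible(list(paths = paths, centiles = cent)))
  }

  # validate
  if (is.null(config$outcomes)) {
    stop("config field 'outcomes' (outcomes CSV) required for validate",
         call. = FALSE)
  }
  outcomes <- utils::read.csv(config$outcomes, stringsAsFactors = FALSE)
  base <- scores[scores$survey_year == 0L, , drop = FALSE]
  m <- merge(base, outcomes, by = "participant_id")
  cox <- cox_fit(m$log_odds, m$event, m$time)
  res <- list(variant = config$variant,
              cox = list(hr_per_10fold = as.list(cox$hr_per_10fold),
                         hr_per_sd = as.list(cox$hr_per_sd),
                         p_value = cox$p_value, n_events = cox$n_events))
  if (!is.null(config$binding)) {
    bind <- utils::read.csv(config$binding, stringsAsFactors = FALSE)
    bind$binding <- select_binding(bind$left, bind$right)
    # pair each scan with the year-2/3 wave, preferring observed data
    pick <- vapply(split(scores, scores$participant_id), function(w) {
      y <- select_imaging_wave(w)
      if (is.na(y)) NA_real_ else w$log_odds[w$survey_year == y]
    }, numeric(1))
    pick <- data.frame(participant_id = names(pick), log_odds = pick,
                       stringsAsFactors = FALSE)
    mb <- merge(bind, pick, by = "participant_id")
    mb <- mb[is.finite(mb$log_odds), , drop = FALSE]
    reg <- binding_regression(mb$log_odds, mb$binding,
                              n_bootstrap = config$n_bootstrap %||% 5000L,
                              seed = config$seed)
    res$binding <- list(r_squared = reg$r_squared,
                        r_squared_ci = as.list(reg$r_squared_ci),
                        slope = as.list(reg$slope), p_value = reg$p_value,
                        nonlinearity_p = reg$nonlinearity_p, n = reg$n)
  }
  p <- file.path(out_dir, sprintf("validation_%s.json", config$variant))
  jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = p, cox = cox,
                 binding = if (!is.null(config$binding)) res$binding))
}
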