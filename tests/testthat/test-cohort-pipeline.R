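mk_waves <- function(years, age0 = 65, ...) {
  extra <- list(...)
  df <- do.call(rbind, lapply(years, function(y) {
    as.data.frame(make_wave(survey_year = y, age = age0 + y),
                  stringsAsFactors = FALSE)
  }))
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df$completed <- TRUE
  df
}

test_that("gaps between observed waves are filled, ageing one year per year", {
  w <- mk_waves(c(0, 2), constipation = c("P", "A"))
  out <- impute_waves(w)
  expect_equal(out$survey_year, c(0, 1, 2))
  expect_equal(out$completed, c(TRUE, FALSE, TRUE))
  # year 1 carries year 0's exposures, one year older
  expect_equal(out$age, c(65, 66, 67))
  expect_equal(out$constipation, c("P", "P", "A"))
})

test_that("no imputation happens after the last observed wave", {
  w <- mk_waves(0)
  out <- impute_waves(w)
  expect_equal(out$survey_year, 0)
  expect_true(all(out$completed))
  # dropout after year 1: years 2+ never appear
  out2 <- impute_waves(mk_waves(c(0, 1)))
  expect_equal(out2$survey_year, c(0, 1))
})

test_that("year 5 is never created even across the year-4 to year-6 gap", {
  out <- impute_waves(mk_waves(c(0, 4, 6)))
  expect_equal(out$survey_year, c(0, 1, 2, 3, 4, 6))
  expect_false(5 %in% out$survey_year)
  # year 6 is observed; the imputed years aged forward from year 0
  expect_equal(out$age, c(65, 66, 67, 68, 69, 71))
})

test_that("smell results carry baseline to years 1-2 and year 3 to years 4 and 6", {
  oc <- paste0("odour_", c("banana", "mint"))
  w <- mk_waves(c(0, 1, 2, 3, 4, 6))
  w[[oc[1]]] <- c(1, NA, NA, 0, NA, NA)
  w[[oc[2]]] <- c(0, NA, NA, 1, NA, NA)
  out <- impute_waves(w)
  expect_equal(out[[oc[1]]], c(1, 1, 1, 0, 0, 0))
  expect_equal(out[[oc[2]]], c(0, 0, 0, 1, 1, 1))

  # no year-3 test: years 4 and 6 get no smell data (multiplier 1)
  w2 <- mk_waves(c(0, 1, 2, 3, 4, 6))
  w2[[oc[1]]] <- c(1, NA, NA, NA, NA, NA)
  w2[[oc[2]]] <- c(1, NA, NA, NA, NA, NA)
  out2 <- impute_waves(w2)
  expect_equal(out2[[oc[1]]], c(1, 1, 1, NA, NA, NA))
})

test_that("pesticide status is back-filled from year 3 to earlier waves", {
  w <- mk_waves(c(0, 1, 2, 3), pesticides = c("U", "U", "U", "P"))
  out <- impute_waves(w)
  expect_equal(out$pesticides, rep("P", 4))
  # without a year-3+ wave the early status stays unknown
  out2 <- impute_waves(mk_waves(c(0, 1), pesticides = c("U", "U")))
  expect_equal(out2$pesticides, c("U", "U"))
})

test_that("imputation is idempotent and preserves observed exposures", {
  w <- mk_waves(c(0, 2, 3, 6), constipation = c("A", "P", "P", "A"),
                pesticides = c("U", "U", "A", "A"))
  w$odour_banana <- c(1, NA, 0, NA)
  once <- impute_waves(w)
  twice <- impute_waves(once)
  expect_identical(once, twice)
  obs <- once[once$completed, ]
  expect_equal(obs$constipation, w$constipation)
  expect_equal(obs$age, w$age)
  imputed_years <- once$survey_year[!once$completed]
  expect_equal(imputed_years, c(1, 4))
  expect_error(impute_waves(mk_waves(c(0, 5))), "year 5")
  expect_error(impute_waves(rbind(w, w[1, ])), "duplicate")
})

test_that("impute_cohort applies the rules participant by participant", {
  w1 <- mk_waves(c(0, 2)); w1$participant_id <- "A"
  w2 <- mk_waves(0); w2$participant_id <- "B"
  out <- impute_cohort(rbind(w1, w2))
  expect_equal(out$survey_year[out$participant_id == "A"], c(0, 1, 2))
  expect_equal(out$survey_year[out$participant_id == "B"], 0)
})

test_that("centile summaries follow the fixed interpolation rule", {
  v <- c(rep(1 / 100, 9), 1 / 10)   # n = 10, one high-risk outlier
  s <- summarize_distribution(v)
  expect_equal(s$fold_90_10,
               quantile_oracle(v, 0.9) / quantile_oracle(v, 0.1))
  expect_equal(s$cent_50, quantile_oracle(v, 0.5))
  expect_equal(s$cent_97_5, quantile_oracle(v, 0.975))

  # all equal: every centile identical and fold differences 1
  s_eq <- summarize_distribution(rep(0.02, 8))
  expect_equal(s_eq$fold_90_10, 1)
  expect_equal(s_eq$fold_75_25, 1)
  expect_equal(s_eq$cent_1, s_eq$cent_99)

  set.seed(3)
  w <- stats::rlnorm(101, -4, 1)
  sw <- summarize_distribution(w)
  cents <- unlist(sw[grep("^cent_", names(sw))])
  expect_true(all(diff(cents) >= 0))
  expect_gte(sw$fold_90_10, 1)
  # quantiles commute with the log transform
  expect_equal(log(sw$cent_90), quantile_oracle(log(w), 0.9),
               tolerance = 1e-12)
  expect_error(summarize_distribution(numeric()), "odds")
  expect_error(summarize_distribution(0.5), "n >= 2")
})

test_that("log-scale histograms preserve counts and bin arithmetic", {
  h1 <- histogram_export(0.013)
  expect_equal(sum(h1$count), 1)
  set.seed(8)
  v <- stats::rlnorm(500, -4, 1.5)
  h <- histogram_export(v, bins_per_decade = 5)
  expect_equal(sum(h$count), 500)
  expect_equal(h$log10_upper - h$log10_lower, rep(0.2, nrow(h)),
               tolerance = 1e-9)
  # values spanning exactly two decades at 5 bins/decade give 10 bins
  h2 <- histogram_export(c(0.001, 0.1), bins_per_decade = 5)
  expect_equal(nrow(h2), 10)
  expect_equal(sum(h2$count), 2)
  expect_error(histogram_export(c(0.1, -1)), "positive")
})

test_that("cohort summaries split by survey year", {
  sim <- small_sim()
  sc <- score_cohort(impute_cohort(sim$waves), algorithm_variant("enhanced16"))
  s <- summarize_cohort(sc)
  expect_setequal(s$survey_year, unique(sc$survey_year))
  expect_true(all(s$fold_90_10 >= s$fold_75_25))
  expect_equal(s$n[s$survey_year == 0], sum(sc$survey_year == 0))
})

test_that("cohort CSVs round-trip through read/write", {
  sim <- small_sim()
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$waves, p)
  back <- read_cohort(p)
  expect_equal(nrow(back), nrow(sim$waves))
  expect_equal(back$age, sim$waves$age, tolerance = 1e-12)
  expect_identical(back$constipation, sim$waves$constipation)
  expect_identical(back$completed, sim$waves$completed)
})
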