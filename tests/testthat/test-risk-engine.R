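enh <- algorithm_variant("enhanced16")
bas <- algorithm_variant("basic")
mds <- algorithm_variant("mds", age_mode = "equation")
models <- default_marker_models()

test_that("enhanced risk multiplies the age prior, sex LR and factor LRs", {
  prior60 <- 1 / 100.998
  r <- compute_risk(make_wave(), enh)
  expect_equal(unclass(r$odds), prior60 * 1.2, tolerance = 1e-12)
  r_f <- compute_risk(make_wave(sex = "female"), enh)
  expect_equal(unclass(r_f$odds), prior60 * 0.8, tolerance = 1e-12)

  r2 <- compute_risk(make_wave(current_smoker = "P", former_smoker = "A",
                               never_smoked = "A", constipation = "P"), enh)
  expect_equal(unclass(r2$odds), prior60 * 1.2 * 0.51 * 2.5,
               tolerance = 1e-12)
  # known absence multiplies by LR- under the enhanced variant
  r3 <- compute_risk(make_wave(constipation = "A"), enh)
  expect_equal(unclass(r3$odds), prior60 * 1.2 * 0.82, tolerance = 1e-12)
})

test_that("basic variant multiplies ORs for present factors only", {
  prior60 <- 1 / 100.998
  r <- compute_risk(make_wave(sex = "female", constipation = "P",
                              coffee = "A", nsaid = "A"), bas)
  # absences contribute nothing under the odds-ratio algorithm
  expect_equal(unclass(r$odds), prior60 * 0.67 * 2.3, tolerance = 1e-12)
  r_m <- compute_risk(make_wave(constipation = "P"), bas)
  expect_equal(unclass(r_m$odds), prior60 * 2.3, tolerance = 1e-12)
  # markers are excluded: tapping and smell leave the basic score unchanged
  w_marked <- make_wave(constipation = "P", ks_raw = 40, at_raw = 140,
                        rbd = "P")
  expect_equal(unclass(compute_risk(w_marked, bas)$odds),
               unclass(r_m$odds), tolerance = 1e-15)
})

test_that("switching one factor moves odds by exactly its tabulated LR", {
  for (f in c("coffee", "constipation", "diabetes", "head_injury", "ccb")) {
    base <- unclass(compute_risk(make_wave(), enh)$odds)
    args_p <- stats::setNames(list("P"), f)
    args_a <- stats::setNames(list("A"), f)
    rp <- unclass(compute_risk(do.call(make_wave, args_p), enh)$odds)
    ra <- unclass(compute_risk(do.call(make_wave, args_a), enh)$odds)
    expect_equal(rp / base, enh$factors[[f]]$lr_pos, tolerance = 1e-12)
    expect_equal(ra / base, enh$factors[[f]]$lr_neg, tolerance = 1e-12)
  }
})

test_that("continuous markers enter the enhanced score and default to 1 when missing", {
  w0 <- make_wave()
  base <- unclass(compute_risk(w0, enh)$odds)
  # tapping
  w_tap <- make_wave(ks_raw = 40, at_raw = 140)
  dm <- to_delta_mom(40, 140, models$mom)
  expect_equal(unclass(compute_risk(w_tap, enh)$odds) / base,
               tapping_lr(dm, models$tapping), tolerance = 1e-12)
  # smell (full 16-item panel, all correct)
  resp <- stats::setNames(as.list(rep(1, 16)),
                          paste0("odour_", names(models$smell16$coefficients)))
  w_sm <- do.call(make_wave, resp)
  expect_equal(unclass(compute_risk(w_sm, enh)$odds) / base,
               smell_lr(stats::setNames(rep(1, 16),
                                        names(models$smell16$coefficients)),
                        models$smell16), tolerance = 1e-12)
  # removing a marker leaves all other multipliers untouched
  b_tap <- compute_risk(w_tap, enh)$breakdown
  b0 <- compute_risk(w0, enh)$breakdown
  expect_equal(b0[["tapping"]], 1)
  expect_equal(b_tap[setdiff(names(b_tap), "tapping")],
               b0[setdiff(names(b0), "tapping")], tolerance = 1e-15)
})

test_that("the enhanced 6-item panel scores with its own smell model", {
  items6 <- names(models$smell6$coefficients)
  resp <- stats::setNames(as.list(rep(0, 6)), paste0("odour_", items6))
  w <- do.call(make_wave, resp)
  e6 <- algorithm_variant("enhanced6")
  base <- unclass(compute_risk(make_wave(), e6)$odds)
  expect_equal(unclass(compute_risk(w, e6)$odds) / base,
               smell_lr(stats::setNames(rep(0, 6), items6), models$smell6),
               tolerance = 1e-12)
  # a 6-item response set does not complete the 16-item panel
  expect_equal(unclass(compute_risk(w, enh)$odds),
               unclass(compute_risk(make_wave(), enh)$odds),
               tolerance = 1e-15)
})

test_that("MDS-style variant applies dichotomous marker LRs", {
  base <- unclass(compute_risk(make_wave(), mds)$odds)
  # impaired tapping beyond threshold: motor present, LR+ 3.5
  w_tap <- make_wave(ks_raw = models$mom$median_ks * 0.7,
                     at_raw = models$mom$median_at)
  expect_equal(unclass(compute_risk(w_tap, mds)$odds) / base, 3.5,
               tolerance = 1e-12)
  # normal tapping at the medians: motor absent, LR- 0.60
  w_ok <- make_wave(ks_raw = models$mom$median_ks,
                    at_raw = models$mom$median_at)
  expect_equal(unclass(compute_risk(w_ok, mds)$odds) / base, 0.60,
               tolerance = 1e-12)
  # all odours correct: olfactory impairment absent, LR- 0.43
  resp <- stats::setNames(as.list(rep(1, 16)),
                          paste0("odour_", names(models$smell16$coefficients)))
  w_sm <- do.call(make_wave, resp)
  expect_equal(unclass(compute_risk(w_sm, mds)$odds) / base, 0.43,
               tolerance = 1e-12)
  # the MDS catalogue prints depression LR- 0.88 (enhanced prints 0.87)
  expect_equal(mds$factors$depression_anxiety$lr_neg, 0.88)
  expect_equal(enh$factors$depression_anxiety$lr_neg, 0.87)
  # categorical age mode without a table is a configuration error
  expect_error(compute_risk(make_wave(), algorithm_variant("mds")),
               "age table|categorical")
})

test_that("profile invariants are enforced", {
  expect_error(compute_risk(make_wave(sex = "unknown"), enh), "sex")
  expect_error(compute_risk(make_wave(current_smoker = "P",
                                      former_smoker = "P",
                                      never_smoked = "A"), enh),
               "mutually exclusive")
  expect_error(compute_risk(make_wave(sex = "female",
                                      erectile_dysfunction = "P"), enh),
               "females")
  # ED absent for a female must not multiply the male-factor LR-
  rf <- compute_risk(make_wave(sex = "female", erectile_dysfunction = "A"),
                     enh)
  expect_equal(rf$breakdown[["erectile_dysfunction"]], 1)
})

test_that("breakdown reconstructs the odds to machine precision", {
  set.seed(42)
  statuses <- c("P", "A", "U")
  factors <- names(enh$factors)
  for (i in 1:200) {
    smoking <- sample(c("current", "former", "never", "unknown"), 1)
    args <- stats::setNames(
      as.list(sample(statuses, length(factors), replace = TRUE)), factors)
    args$current_smoker <- if (smoking == "current") "P"
    else if (smoking == "unknown") "U" else "A"
    args$former_smoker <- if (smoking == "former") "P"
    else if (smoking == "unknown") "U" else "A"
    args$never_smoked <- if (smoking == "never") "P"
    else if (smoking == "unknown") "U" else "A"
    args$age <- stats::runif(1, 60, 90)
    args$sex <- sample(c("male", "female"), 1)
    if (args$sex == "female" && args$erectile_dysfunction == "P") {
      args$erectile_dysfunction <- "A"
    }
    if (stats::runif(1) < 0.5) {
      args$ks_raw <- stats::runif(1, 30, 80)
      args$at_raw <- stats::runif(1, 60, 160)
    }
    r <- compute_risk(do.call(make_wave, args), enh)
    expect_equal(unclass(r$odds), prod(r$breakdown),
                 tolerance = 1e-12)
  }
})

test_that("basic and enhanced agree in ranking when tables are order-isomorphic", {
  # construct an order-isomorphic catalogue: LR+ a strictly increasing
  # transform of the OR for every shared factor
  tabs <- default_factor_tables()
  shared <- names(tabs$basic$factors)
  for (f in shared) {
    or <- tabs$basic$factors[[f]]$or
    tabs$enhanced$factors[[f]]$lr_pos <- or^0.8
  }
  v_iso <- algorithm_variant("enhanced16", tables = tabs)
  v_bas <- algorithm_variant("basic", tables = tabs)
  set.seed(9)
  score_pair <- function(variant) {
    vapply(profiles, function(pr) unclass(compute_risk(pr, variant)$odds),
           numeric(1))
  }
  profiles <- lapply(1:60, function(i) {
    present <- sample(shared, sample(3:8, 1))
    args <- stats::setNames(as.list(rep("P", length(present))), present)
    # keep smoking exclusive and sex fixed so only the factor set varies
    args$former_smoker <- NULL; args$never_smoked <- NULL
    args$erectile_dysfunction <- NULL
    do.call(make_wave, args)
  })
  rho_iso <- stats::cor(score_pair(v_iso), score_pair(v_bas),
                        method = "spearman")
  expect_equal(rho_iso, 1, tolerance = 1e-12)
  # the shipped tables are close to, but not exactly, order-isomorphic
  v_ship <- algorithm_variant("enhanced16")
  v_ship_bas <- algorithm_variant("basic")
  rho_ship <- stats::cor(score_pair(v_ship), score_pair(v_ship_bas),
                         method = "spearman")
  expect_gt(rho_ship, 0.9)
})

test_that("risk trajectories require ordered waves and score each wave", {
  waves <- do.call(rbind, lapply(0:2, function(y) {
    as.data.frame(make_wave(survey_year = y, age = 65 + y),
                  stringsAsFactors = FALSE)
  }))
  tr <- risk_trajectory(waves, enh)
  expect_length(tr, 3)
  expect_equal(unclass(tr[[2]]$odds),
               unclass(compute_risk(make_wave(survey_year = 1, age = 66),
                                    enh)$odds))
  expect_true(all(diff(vapply(tr, function(r) unclass(r$odds),
                              numeric(1))) > 0))
  expect_error(risk_trajectory(waves[c(2, 1, 3), ], enh), "ordered")
  expect_error(risk_trajectory(rbind(waves, waves[1, ]), enh), "ordered")
  single <- risk_trajectory(waves[1, , drop = FALSE], enh)
  expect_length(single, 1)
})

test_that("an incomplete variant table raises a configuration error naming factors", {
  tabs <- default_factor_tables()
  tabs$enhanced$factors$coffee <- NULL
  tabs$enhanced$factors$diabetes$lr_pos <- NULL
  expect_error(algorithm_variant("enhanced16", tables = tabs),
               "coffee.*diabetes|diabetes.*coffee")
})
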