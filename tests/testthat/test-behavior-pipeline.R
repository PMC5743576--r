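test_that("time-weighted mean perch matches hand-computed values", {
  expect_equal(time_weighted_mean_perch(c(100, 0), c(10, 10)), 50)
  expect_equal(time_weighted_mean_perch(73.2, 4), 73.2)
  # (20*5 + 60*15) / 20 = 50
  expect_equal(time_weighted_mean_perch(c(20, 60), c(5, 15)), 50)
  expect_error(time_weighted_mean_perch(numeric(0), numeric(0)), "no perch")
  expect_error(time_weighted_mean_perch(c(10, -1), c(1, 1)), ">= 0")
  expect_error(time_weighted_mean_perch(c(10, 10), c(1, 0)), "> 0")
})

test_that("time-weighted mean is invariant to splitting events", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    h <- stats::runif(n, 0, 150)
    d <- stats::runif(n, 0.5, 5)
    # split every event into two sub-events at the same height
    frac <- stats::runif(n, 0.1, 0.9)
    h2 <- rep(h, each = 2)
    d2 <- as.vector(rbind(d * frac, d * (1 - frac)))
    expect_equal(time_weighted_mean_perch(h, d),
                 time_weighted_mean_perch(h2, d2))
  }
})

test_that("activity classification is strict at 0.8 moves per minute", {
  expect_identical(classify_activity(8, 10), "inactive")  # exactly 0.8
  expect_identical(classify_activity(9, 10), "active")
  expect_identical(classify_activity(0, 15), "inactive")
  expect_identical(classify_activity(c(8, 9, 0), c(10, 10, 15)),
                   c("inactive", "active", "inactive"))
  expect_error(classify_activity(1, 0), "> 0")
})

test_that("bout summaries collapse events with correct rates and weighting", {
  tab <- make_bout_table(
    list(ev(c(20, 60), c(5, 15)), ev(c(100, 0), c(10, 10))),
    n_moves = c(9, 8), n_attacks = c(3, 0), duration_min = c(20, 20),
    distance = c(NA, 120))
  s <- summarize_bouts(tab)
  expect_equal(nrow(s), 2)
  expect_equal(s$tw_mean_perch, c(50, 50))
  expect_equal(s$move_rate, c(0.45, 0.4))
  expect_equal(s$attack_rate, c(0.15, 0))
  expect_identical(s$activity, c("inactive", "inactive"))
  expect_equal(s$mean_distance_cm, c(NA, 120))
})

test_that("rates halve when all dwells and duration double at fixed counts", {
  base <- make_bout_table(list(ev(c(30, 50), c(4, 6))), n_moves = 9,
                          n_attacks = 2, duration_min = 10)
  doubled <- make_bout_table(list(ev(c(30, 50), c(8, 12))), n_moves = 9,
                             n_attacks = 2, duration_min = 20)
  s1 <- summarize_bouts(base)
  s2 <- summarize_bouts(doubled)
  expect_equal(s2$move_rate, s1$move_rate / 2)
  expect_equal(s2$attack_rate, s1$attack_rate / 2)
  expect_equal(s2$tw_mean_perch, s1$tw_mean_perch)
})

test_that("bout table validation catches schema violations", {
  tab <- make_bout_table(list(ev(c(10, 20), c(5, 5))))
  expect_silent(validate_bout_table(tab))
  bad <- tab; bad$height_cm[1] <- -2
  expect_error(validate_bout_table(bad), ">= 0")
  bad <- tab; bad$duration_min <- 25
  expect_error(validate_bout_table(bad), "\\(0, 20\\]")
  bad <- tab; bad$dwell_min <- c(15, 15)  # 30 min dwell in a 10 min bout
  expect_error(validate_bout_table(bad), "exceed")
  bad <- tab; bad$treatment[1] <- "exposed"
  expect_error(validate_bout_table(bad), "treatment")
  expect_error(validate_bout_table(tab[, -3]), "missing columns")
})

test_that("bout tables round-trip through CSV", {
  tab <- make_bout_table(list(ev(c(10, 20), c(5, 5)), ev(35, 8)),
                         distance = c(50, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_bout_table(tab, path)
  back <- read_bout_table(path)
  expect_equal(back$height_cm, tab$height_cm)
  expect_equal(back$distance_to_seaweed_cm, tab$distance_to_seaweed_cm)
  expect_equal(summarize_bouts(back)$tw_mean_perch,
               summarize_bouts(tab)$tw_mean_perch)
})

test_that("gamma fitting matches the fitdistrplus oracle", {
  skip_if_not_installed("fitdistrplus")
  set.seed(51)
  x <- stats::rgamma(400, shape = 2.3, scale = 31)
  x_active <- stats::rgamma(30, shape = 2, scale = 12)
  tab <- make_bout_table(lapply(c(x_active, x), function(h) ev(h, 10)),
                         duration_min = 10,
                         n_moves = rep(c(12L, 2L), c(30, 400)))
  em <- fit_emission_model(tab, control_only = FALSE)
  oracle <- fitdistrplus::fitdist(x, "gamma", method = "mle")
  # agreement limited by the oracle optimizer's own convergence tolerance
  expect_equal(em$inactive_shape, unname(oracle$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(em$inactive_scale, 1 / unname(oracle$estimate["rate"]),
               tolerance = 1e-3)
})

test_that("fitted emission means converge to the truth as n grows", {
  em_true <- emission_model()
  errs <- sapply(c(50, 500, 5000), function(n) {
    tab <- make_classified_bouts(n, em_true, seed = n)
    em <- fit_emission_model(tab)
    m <- emission_means(em)
    max(abs(m / emission_means(em_true) - 1))
  })
  expect_true(all(diff(errs) < 0))     # shrinking error
  expect_lt(errs[3], 0.05)
  # per-state sample sizes are reported
  tab <- make_classified_bouts(100, em_true, seed = 1)
  expect_equal(unname(attr(fit_emission_model(tab), "n")),
               c(100, 100))
})

test_that("emission fitting rejects degenerate and insufficient data", {
  tab <- make_bout_table(lapply(rep(40, 10), function(h) ev(h, 10)),
                         duration_min = 10, n_moves = rep(c(12L, 2L), 5))
  expect_error(fit_emission_model(tab), "degenerate|variance")
  # only two active bouts
  tab2 <- make_classified_bouts(20, emission_model(), seed = 3)
  tab2 <- tab2[c(1:2, 21:40) , ]
  expect_error(fit_emission_model(tab2), "insufficient|fewer")
  # treatment-only data filtered away
  tab3 <- make_classified_bouts(10, emission_model(), seed = 4)
  tab3$treatment <- "treatment"
  expect_error(fit_emission_model(tab3), "control")
})

test_that("presubsidy baselines average presubsidy bouts only, per plot", {
  tab <- make_bout_table(
    list(ev(40, 10), ev(60, 10), ev(200, 10)),
    time_since_subsidy_min = c(-30, -90, 120))
  s <- summarize_bouts(tab)
  b <- presubsidy_baseline(s, "perch")
  expect_equal(b$baseline, 50)  # postsubsidy 200 cm bout excluded
  # a plot without presubsidy bouts is named in the error
  tab2 <- make_bout_table(list(ev(40, 10), ev(10, 10)),
                          plot_id = c("B1P1", "B9P9"),
                          time_since_subsidy_min = c(-30, 60))
  expect_error(presubsidy_baseline(summarize_bouts(tab2), "perch"), "B9P9")
})

test_that("interaction statistic is invariant to relabelling the arms", {
  st <- generate_study(study_config(seed = 8))
  s <- summarize_bouts(st)
  flipped <- s
  flipped$treatment <- ifelse(s$treatment == "control", "treatment", "control")
  r1 <- test_treatment_by_time(s, "perch")
  r2 <- test_treatment_by_time(flipped, "perch")
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-6)
  expect_equal(r1$df, 1)
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  expect_equal(r1$alpha, 0.05)
})

test_that("treatment tests detect the generator's injected pulse response", {
  st <- generate_study(study_config(seed = 5))
  s <- summarize_bouts(st)
  perch <- test_treatment_by_time(s, "perch")
  moves <- test_treatment_by_time(s, "moves")
  expect_lt(perch$p_value, 0.05)
  expect_lt(moves$p_value, 0.05)
  expect_equal(moves$df, 1)
  # the perch response declines in treated plots: interaction recovers sign
  expect_gt(unname(lme4::fixef(perch$full_fit)["treatmenttreatment:time_h"]), 0)
})

test_that("design violations raise errors rather than silent misfits", {
  st <- generate_study(study_config(seed = 9))
  s <- summarize_bouts(st)
  one_arm <- s[s$treatment == "control", ]
  expect_error(test_treatment_by_time(one_arm, "perch"), "both arms")
  no_dist <- s; no_dist$mean_distance_cm <- NA_real_
  expect_error(test_perch_vs_distance(no_dist), "distance")
  const_dist <- s; const_dist$mean_distance_cm <- 100
  expect_error(test_perch_vs_distance(const_dist), "degenerate")
  one_stage <- s; one_stage$stage <- "large"
  expect_error(test_stage_interaction(one_stage, "perch"), "stage")
})

test_that("distance model recovers a positive built-in slope", {
  st <- generate_study(study_config(seed = 14))
  s <- summarize_bouts(st)
  res <- test_perch_vs_distance(s)
  expect_gt(res$slope, 0)
  expect_equal(res$df, 1)
  expect_true(res$n > 10)
})

test_that("stage interaction test runs under the null and reports df 1", {
  st <- generate_study(study_config(seed = 15))
  s <- summarize_bouts(st)
  res <- test_stage_interaction(s, "perch")
  expect_equal(res$df, 1)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  res_m <- test_stage_interaction(s, "moves")
  expect_equal(res_m$df, 1)
})
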