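# Hierarchical Bayesian fit: sampling contract, diagnostics, determinism,
# agreement with direct per-subject maximum likelihood.

small_fit <- function(cohort, seed = 3, ...) {
  suppressWarnings(
    fit_happiness_hier(cohort$sessions, chains = 2, adapt = 200,
                       warmup = 200, iter = 250, seed = seed,
                       standardize = FALSE, ...))
}

test_that("prior-predictive gamma spans the unit interval", {
  set.seed(73)
  pri <- prior_config()
  g <- plogis(rnorm(5000, pri$mean_loc, pri$mean_scale))
  expect_true(all(g > 0 & g < 1))
  expect_lt(min(g), 0.05)
  expect_gt(max(g), 0.95)
  expect_error(prior_config(sd_scale = -1), "sd_scale")
})

test_that("the sampler honors its contract: shapes, gamma range, diagnostics, seeds", {
  co <- make_small_cell(n_subjects = 3, n_trials = 100, seed = 19)
  fit <- small_fit(co)
  expect_s3_class(fit, "sborg_hfit")
  expect_equal(fit$subjects, vapply(co$sessions, function(s)
    s$subject_id[1], character(1)))

  m <- group_draws(fit)
  expect_equal(colnames(m), c("w0", "w1", "w2", "w3", "gamma"))
  expect_equal(nrow(m), 2 * 250)             # equal retained counts
  expect_true(all(m[, "gamma"] >= 0 & m[, "gamma"] <= 1))
  # every individual-level forgetting factor stays in [0, 1] too
  all_draws <- do.call(rbind, lapply(fit$draws, as.matrix))
  gam_cols <- grep("^gam\\[", colnames(all_draws), value = TRUE)
  expect_length(gam_cols, 3)
  expect_true(all(all_draws[, gam_cols] >= 0 & all_draws[, gam_cols] <= 1))

  # diagnostics populated for every sampled quantity
  expect_true(all(colnames(all_draws) %in% fit$diagnostics$parameter))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$ess > 0))
  expect_true(is.na(fit$settings$divergences))

  # fixed seed and settings reproduce draws exactly
  fit2 <- small_fit(co)
  expect_identical(lapply(fit$draws, as.matrix),
                   lapply(fit2$draws, as.matrix))
  fit3 <- small_fit(co, seed = 4)
  expect_false(identical(lapply(fit$draws, as.matrix),
                         lapply(fit3$draws, as.matrix)))
})

test_that("degenerate and under-rated sessions are excluded with a warning", {
  co <- make_small_cell(n_subjects = 3, n_trials = 100, seed = 23)
  flat <- make_session(choices = rep("certain", 30), outcomes = rep(3, 30),
                       ratings = setNames(rep(2, 10), seq(3, 30, by = 3)),
                       subject_id = "FLAT", group = "non-ICD",
                       med_state = "off")
  msgs <- capture_warnings(
    fit <- fit_happiness_hier(c(co$sessions, list(flat)), chains = 1,
                              adapt = 150, warmup = 100, iter = 100,
                              seed = 5, standardize = TRUE))
  expect_true(any(grepl("degenerate", msgs)))
  expect_equal(fit$excluded, "FLAT")
  expect_false("FLAT" %in% fit$subjects)

  expect_error(
    suppressWarnings(fit_happiness_hier(list(flat), seed = 1)),
    "at least 2")
})

test_that("individual posterior means agree with direct per-subject ML optima", {
  co <- make_small_cell(n_subjects = 2, n_trials = 400, seed = 29)
  fit <- suppressWarnings(
    fit_happiness_hier(co$sessions, chains = 2, adapt = 300, warmup = 300,
                       iter = 400, seed = 7, standardize = FALSE,
                       priors = prior_config(mean_scale = 5, sd_scale = 0.5)))
  ind <- individual_means(fit)
  all_draws <- do.call(rbind, lapply(fit$draws, as.matrix))
  for (s in 1:2) {
    reg <- build_regressors(co$sessions[[s]])
    ml <- oracle_ml_happiness(reg, reg$rating[reg$rated], which(reg$rated))
    for (p in 1:4) {
      post_sd <- sd(all_draws[, sprintf("w[%d,%d]", s, p)])
      expect_lt(abs(ind[[c("w0", "w1", "w2", "w3")[p]]][s] - ml[p]),
                3 * post_sd + 0.02)
    }
  }
})

test_that("with homogeneous truth, individual estimates shrink below their ML spread", {
  groups <- sborg_presets(n_icd = 4, n_nonicd = 4)
  g <- groups$nonicd_off
  g$sds <- lapply(g$sds, function(x) 0)      # zero simulated heterogeneity
  co <- simulate_cohort(list(g), task_config(n_trials = 120), seed = 31)
  fit <- suppressWarnings(
    fit_happiness_hier(co$sessions, chains = 1, adapt = 200, warmup = 200,
                       iter = 300, seed = 11, standardize = FALSE,
                       priors = prior_config(sd_scale = 0.05)))
  ind <- individual_means(fit)
  ml_w1 <- vapply(co$sessions, function(ses) {
    reg <- build_regressors(ses)
    oracle_ml_happiness(reg, reg$rating[reg$rated], which(reg$rated))[["w1"]]
  }, numeric(1))
  expect_lt(sd(ind$w1), sd(ml_w1))
})

test_that("posterior_summary reports mean, sd, and HDI per parameter", {
  s <- posterior_summary(list(a = rep(2.5, 100)))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 0)
  expect_equal(c(s$hdi_low, s$hdi_high), c(2.5, 2.5))

  set.seed(79)
  s2 <- posterior_summary(list(z = rnorm(1e5)))
  expect_equal(s2$mean, 0, tolerance = 0.02)
  expect_equal(s2$hdi_low, -1.96, tolerance = 0.05)
  expect_equal(s2$hdi_high, 1.96, tolerance = 0.05)

  m <- cbind(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  expect_equal(nrow(posterior_summary(m)), 3)
})

test_that("predict_from_fit covers exactly the rated trials of known subjects", {
  co <- make_small_cell(n_subjects = 3, n_trials = 100, seed = 37)
  fit <- small_fit(co, seed = 13)
  pred <- predict_from_fit(fit, co$sessions)
  n_rated <- sum(vapply(co$sessions, function(s)
    sum(!is.na(s$rating)), integer(1)))
  expect_equal(nrow(pred), n_rated)
  expect_true(all(is.finite(pred$predicted)))

  stranger <- co$sessions[[1]]
  stranger$subject_id <- "NOPE"
  expect_error(predict_from_fit(fit, list(stranger)), "not covered")
})

test_that("tidy_draws emits one row per chain/draw/parameter", {
  co <- make_small_cell(n_subjects = 2, n_trials = 60, seed = 41)
  fit <- suppressWarnings(
    fit_happiness_hier(co$sessions, chains = 2, adapt = 150, warmup = 100,
                       iter = 100, seed = 17, standardize = FALSE))
  td <- tidy_draws(fit)
  expect_named(td, c("chain", "draw", "parameter", "value"))
  n_par <- nrow(fit$diagnostics)
  expect_equal(nrow(td), 2 * 100 * n_par)
})
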