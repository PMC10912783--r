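# Gamble-choice model: design table construction, logistic fits, group tests.

test_that("build_choice_table enumerates rated_only rows exactly", {
  # prompts on trials 2 and 5 -> usable rows are trials 3 and 6 only
  ses <- make_session(
    choices = rep(c("certain", "gamble"), 5),
    outcomes = c(3, 5, 3, 1, 3, 5, 3, 1, 3, 5),
    ratings = c(`2` = 1.2, `5` = -0.4))
  tab <- build_choice_table(ses, "rated_only", standardize = FALSE)
  expect_equal(tab$trial_index, c(3, 6))
  expect_equal(tab$SR_H_prev, c(1.2, -0.4))
  expect_equal(tab$gamble_chosen, c(0, 1))
  expect_equal(tab$EV_G, c(3, 3))
  expect_equal(tab$EV_CR, c(3, 3))

  # every trial rated -> rows for responded trials 2..T; trial 1 never enters
  all_rated <- make_session(
    choices = rep("gamble", 12), outcomes = rep(5, 12),
    ratings = setNames(rnorm(12), 1:12))
  tab2 <- build_choice_table(all_rated, "rated_only", standardize = FALSE)
  expect_equal(tab2$trial_index, 2:12)

  # zero prompts -> empty table with a warning
  none <- make_session(choices = rep("certain", 12), outcomes = rep(3, 12))
  expect_warning(tab3 <- build_choice_table(none, "rated_only"),
                 "no rated trials")
  expect_equal(nrow(tab3), 0)
})

test_that("locf carries the most recent rating forward", {
  ses <- make_session(
    choices = c("certain", "gamble", "certain", "timeout", "gamble",
                "certain", "gamble"),
    outcomes = c(3, 5, 3, NA, 1, 3, 5),
    ratings = c(`2` = 0.8, `6` = -1.1))
  tab <- build_choice_table(ses, "locf", standardize = FALSE)
  # responded trials after the first rating: 3, 5, 6, 7
  expect_equal(tab$trial_index, c(3, 5, 6, 7))
  expect_equal(tab$SR_H_prev, c(0.8, 0.8, 0.8, -1.1))
})

test_that("logistic fit recovers generative coefficients (simulation)", {
  set.seed(83)
  n <- 5000
  ev_g <- gamble_ev(sample(0:6, n, TRUE), sample(0:6, n, TRUE))
  ev_cr <- sample(1:6, n, TRUE)
  sr <- rnorm(n)
  truth <- c(0.3, 1.2, -1.1, 0.4)
  p <- plogis(truth[1] + truth[2] * ev_g + truth[3] * ev_cr + truth[4] * sr)
  rows <- data.frame(gamble_chosen = rbinom(n, 1, p), EV_G = ev_g,
                     EV_CR = ev_cr, SR_H_prev = sr)
  fit <- fit_logistic_choice(rows)
  expect_true(fit$converged)
  expect_false(fit$separation)
  for (k in 1:4)
    expect_lt(abs(fit$coef[[k]] - truth[k]), 3 * fit$se[[k]])
})

test_that("perfect separation trips the guard instead of silent shrinkage", {
  rows <- data.frame(
    gamble_chosen = rep(c(1L, 0L), each = 10),
    EV_G = c(rep(6, 10), rep(0, 10)),
    EV_CR = c(rep(1, 10), rep(6, 10)),
    SR_H_prev = 0)
  expect_warning(fit <- fit_logistic_choice(rows), "separation")
  expect_true(fit$separation)
})

test_that("fit preconditions are enforced", {
  rows <- data.frame(gamble_chosen = rep(1L, 30), EV_G = rnorm(30),
                     EV_CR = rnorm(30), SR_H_prev = rnorm(30))
  expect_error(fit_logistic_choice(rows), "single-class")
  expect_error(fit_logistic_choice(rows[1:5, ]), "at least 10")
})

test_that("a null previous-rating effect is rejected at the nominal rate", {
  set.seed(89)
  n <- 400
  hits <- replicate(60, {
    ev_g <- gamble_ev(sample(0:6, n, TRUE), sample(0:6, n, TRUE))
    ev_cr <- sample(1:6, n, TRUE)
    sr <- rnorm(n)
    p <- plogis(0.2 + 1 * ev_g - 1 * ev_cr)   # beta3 = 0 generative
    rows <- data.frame(gamble_chosen = rbinom(n, 1, p), EV_G = ev_g,
                       EV_CR = ev_cr, SR_H_prev = sr)
    fit <- suppressWarnings(fit_logistic_choice(rows))
    abs(fit$coef[["beta3"]] / fit$se[["beta3"]]) > 1.96
  })
  # ~5% type-I errors; 3 binomial SEs around 0.05 at 60 replicates
  expect_lt(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("group coefficient test matches the textbook formula to 1e-10", {
  set.seed(97)
  x <- rnorm(12, 2.3, 0.6)
  res <- group_coefficient_test(x)
  ora <- oracle_t_test(x)
  expect_equal(res$estimate, mean(x), tolerance = 1e-12)
  expect_equal(res$t_statistic, ora$t, tolerance = 1e-10)
  expect_equal(res$p_value, ora$p, tolerance = 1e-10)
  expect_equal(c(res$ci_low, res$ci_high), ora$ci, tolerance = 1e-10)

  # symmetric-about-zero coefficients carry no direction
  sym <- c(-2, -1, -0.5, 0.5, 1, 2)
  expect_gt(group_coefficient_test(sym)$p_value, 0.99)

  # identical coefficients: zero-width CI, t undefined, flagged
  expect_warning(flat <- group_coefficient_test(rep(1.5, 6)), "zero variance")
  expect_true(flat$zero_variance)
  expect_equal(flat$estimate, 1.5)
  expect_true(is.na(flat$t_statistic))
  expect_error(group_coefficient_test(2), "at least 2")
})

test_that("cohort-level choice fitting produces a cell-by-coefficient summary", {
  co <- simulate_cohort(sborg_presets(n_icd = 4, n_nonicd = 4),
                        task_config(n_trials = 150), seed = 53)
  coefs <- suppressWarnings(fit_choice_cohort(cell_sessions(co, NULL, "off"),
                                              standardize = FALSE))
  expect_true(all(c("beta0", "beta1", "beta2", "beta3") %in% names(coefs)))
  summ <- choice_group_summary(coefs)
  expect_setequal(unique(summ$group), c("ICD", "non-ICD"))
  # gamble EV attracts, certain value repels, in every cell
  expect_true(all(summ$estimate[summ$coefficient == "beta1"] > 0))
  expect_true(all(summ$estimate[summ$coefficient == "beta2"] < 0))
})
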