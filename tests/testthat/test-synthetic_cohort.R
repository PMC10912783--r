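# Synthetic cohort generator: agent draws, session simulation, cohorts.

zero_sds <- function() {
  s <- default_group_sds()
  lapply(s, function(x) 0)
}

test_that("degenerate hierarchy: zero sds reproduce the group means exactly", {
  g <- group_spec("ICD", "off", 4,
                  means = list(w0 = -0.6, w1 = 0.14, w2 = 0.11, w3 = 0.33,
                               gamma = 0.5, rating_noise_sd = 0.5,
                               beta0 = 0.1, beta1 = 2, beta2 = -2,
                               beta3 = 0),
                  sds = zero_sds())
  a <- draw_agent(g, seed = 1)
  expect_equal(a$happiness$w0, -0.6)
  expect_equal(a$happiness$w1, 0.14)
  expect_equal(a$happiness$gamma, 0.5)  # logistic-map midpoint
  expect_equal(a$choice$beta1, 2)
  expect_equal(a$happiness$rating_noise_sd, 0.5)
})

test_that("agent parameters are normal around the group mean (Monte Carlo)", {
  g <- group_spec("non-ICD", "off", 1)
  set.seed(5)
  w1 <- replicate(1e4, draw_agent(g)$happiness$w1)
  expect_lt(abs(mean(w1) - g$means$w1), 3 * g$sds$w1 / 100)
  expect_lt(abs(sd(w1) - g$sds$w1), 0.005)
  gam <- replicate(2000, draw_agent(g)$happiness$gamma)
  expect_true(all(gam > 0 & gam < 1))
})

test_that("deterministic logistic limit picks the higher-EV option on conflict trials", {
  g <- group_spec("ICD", "off", 1,
                  means = list(w0 = 0, w1 = 0, w2 = 0, w3 = 0, gamma = 0.5,
                               rating_noise_sd = 0.5, beta0 = 0,
                               beta1 = 50, beta2 = -50, beta3 = 0),
                  sds = zero_sds(), timeout_prob = 0)
  agent <- draw_agent(g, seed = 2)
  sch <- generate_schedule(task_config(n_trials = 300, seed = 9,
                                       dominated_fraction = 0))
  ses <- simulate_session(agent, sch, seed = 3)
  ev <- gamble_ev(ses$gamble_low, ses$gamble_high)
  decided <- ev != ses$certain_value     # EV ties stay stochastic
  expect_true(all((ses$choice == "gamble")[decided] ==
                    (ev > ses$certain_value)[decided]))
})

test_that("all-zero choice weights gamble at 50% and outcomes split 50/50", {
  g <- group_spec("ICD", "off", 1,
                  means = list(w0 = 0, w1 = 0, w2 = 0, w3 = 0, gamma = 0.5,
                               rating_noise_sd = 0.5, beta0 = 0, beta1 = 0,
                               beta2 = 0, beta3 = 0),
                  sds = zero_sds(), timeout_prob = 0)
  agent <- draw_agent(g, seed = 2)
  sch <- generate_schedule(task_config(n_trials = 8000, seed = 10))
  ses <- simulate_session(agent, sch, seed = 4)
  p_gamble <- mean(ses$choice == "gamble")
  expect_lt(abs(p_gamble - 0.5), 3 * sqrt(0.25 / 8000))
  # gamble outcomes split 50/50 between low and high (strict gambles only)
  gb <- ses[ses$choice == "gamble" & ses$gamble_low < ses$gamble_high, ]
  p_high <- mean(gb$outcome == gb$gamble_high)
  expect_lt(abs(p_high - 0.5), 3 * sqrt(0.25 / nrow(gb)))
})

test_that("noise-free intercept-only agent rates exactly w0", {
  g <- group_spec("ICD", "off", 1,
                  means = list(w0 = 0.7, w1 = 0, w2 = 0, w3 = 0, gamma = 0.5,
                               rating_noise_sd = 1e-9, beta0 = 0, beta1 = 0,
                               beta2 = 0, beta3 = 0),
                  sds = zero_sds(), timeout_prob = 0)
  agent <- draw_agent(g, seed = 2)
  ses <- simulate_session(agent, generate_schedule(task_config(100, seed = 12)),
                          seed = 5)
  r <- ses$rating[!is.na(ses$rating)]
  expect_gt(length(r), 10)
  expect_equal(r, rep(0.7, length(r)), tolerance = 1e-6)
})

test_that("ratings appear only on prompted, non-timeout trials and timeouts match their rate", {
  g <- group_spec("ICD", "off", 1, timeout_prob = 0.1)
  agent <- draw_agent(g, seed = 7)
  ses <- simulate_session(agent, generate_schedule(task_config(5000, seed = 14)),
                          seed = 6)
  has_rating <- !is.na(ses$rating)
  expect_true(all(ses$rating_prompt[has_rating]))
  expect_true(all(ses$choice[has_rating] != "timeout"))
  expect_true(all(is.na(ses$outcome[ses$choice == "timeout"])))
  p_to <- mean(ses$choice == "timeout")
  expect_lt(abs(p_to - 0.1), 3 * sqrt(0.1 * 0.9 / 5000))
})

test_that("slider mode emits -4..+4 integers", {
  g <- group_spec("ICD", "off", 1)
  agent <- draw_agent(g, seed = 3)
  ses <- simulate_session(agent, generate_schedule(task_config(400, seed = 15)),
                          seed = 8, rating_scale = "slider")
  r <- ses$rating[!is.na(ses$rating)]
  expect_true(all(r == round(r) & r >= -4 & r <= 4))
})

test_that("cohort bookkeeping: session counts, manifest join, determinism", {
  # full design: 18 ICD + 12 non-ICD, both medication states -> 60 sessions
  co <- simulate_cohort(sborg_presets(), task_config(n_trials = 4), seed = 31)
  expect_length(co$sessions, 60)
  expect_equal(nrow(co$manifest), 60)
  expect_equal(nrow(co$manifest),
               sum(vapply(sborg_presets(), `[[`, integer(1), "n_subjects")))
  keys_m <- paste(co$manifest$subject_id, co$manifest$med_state)
  keys_s <- vapply(co$sessions, function(s)
    paste(s$subject_id[1], s$med_state[1]), character(1))
  expect_setequal(keys_m, keys_s)

  # empty group list -> empty outputs, no error
  empty <- simulate_cohort(list(), seed = 1)
  expect_length(empty$sessions, 0)
  expect_equal(nrow(empty$manifest), 0)

  # full determinism under a fixed seed
  a <- simulate_cohort(sborg_presets(n_icd = 2, n_nonicd = 2),
                       task_config(n_trials = 30), seed = 99)
  b <- simulate_cohort(sborg_presets(n_icd = 2, n_nonicd = 2),
                       task_config(n_trials = 30), seed = 99)
  expect_identical(a, b)
  expect_error(simulate_cohort(sborg_presets(), seed = NULL), "seed")
})

test_that("cell_sessions filters by group and medication state", {
  co <- simulate_cohort(sborg_presets(n_icd = 2, n_nonicd = 3),
                        task_config(n_trials = 4), seed = 17)
  expect_length(cell_sessions(co, "ICD", "off"), 2)
  expect_length(cell_sessions(co, "non-ICD", "on"), 3)
  expect_length(cell_sessions(co, "non-ICD", NULL), 6)
})
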