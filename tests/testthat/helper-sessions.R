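# Small deterministic fixtures built in code.

# A hand-built session: explicit choices/outcomes/ratings for enumeration
# oracles.  `ratings` is a named vector keyed by trial index.
make_session <- function(choices, outcomes, ratings = numeric(0),
                         certain = NULL, g_low = NULL, g_high = NULL,
                         subject_id = "T1", group = "ICD",
                         med_state = "off") {
  n <- length(choices)
  if (is.null(certain)) certain <- rep(3L, n)
  if (is.null(g_low)) g_low <- rep(1L, n)
  if (is.null(g_high)) g_high <- rep(5L, n)
  rating <- rep(NA_real_, n)
  if (length(ratings)) rating[as.integer(names(ratings))] <- ratings
  out <- data.frame(
    subject_id = subject_id, group = group, med_state = med_state,
    trial_index = seq_len(n), certain_value = certain,
    gamble_low = g_low, gamble_high = g_high,
    rating_prompt = !is.na(rating), time_limit = 6L,
    dominance_class = classify_trial(certain, g_low, g_high),
    choice = choices, outcome = outcomes, rating = rating)
  class(out) <- c("sborg_session", "data.frame")
  out
}

# A simulated single-cell cohort at reduced size, ratings on the z-scale.
make_small_cell <- function(n_subjects = 3, n_trials = 100, seed = 42,
                            preset = "nonicd_off") {
  groups <- sborg_presets(n_icd = n_subjects, n_nonicd = n_subjects)
  simulate_cohort(groups[preset], task_config(n_trials = n_trials),
                  seed = seed)
}
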