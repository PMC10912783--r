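#!/usr/bin/env Rscript
# Stage 4 — per-subject logistic gamble-choice fits and group summaries.
#
# The decision to gamble is regressed on the gamble's expected value, the
# certain amount, and the previous subjective rating.  Two modes for the
# previous rating: `rated_only` keeps trials immediately preceded by a
# rating (~a third of trials; prone to quasi-separation at session length),
# `locf` carries the most recent rating forward over all responded trials.
# Per-subject coefficients are averaged per cell with one-sample t-tests.

library(sborg)

out <- "results/analysis"
sessions <- read_sessions(file.path(out, "sessions.csv"))

for (mode in c("rated_only", "locf")) {
  coefs <- fit_choice_cohort(sessions, prev_rating_mode = mode,
                             standardize = FALSE)
  write_table(coefs, file.path(out, paste0("choice_coefficients_", mode,
                                           ".csv")))
  summ <- choice_group_summary(coefs)
  write_table(summ, file.path(out, paste0("choice_group_summary_", mode,
                                          ".csv")))
  cat("\n== mode:", mode, "(", sum(coefs$separation), "separation flags /",
      nrow(coefs), "fits ) ==\n")
  print(summ[summ$coefficient %in% c("beta1", "beta2"),
             c("group", "med_state", "coefficient", "estimate",
               "ci_low", "ci_high", "p_value")], digits = 3)
}
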