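#!/usr/bin/env Rscript
# Stage 3 — group-level posterior comparisons.
#
# ICD vs non-ICD within each medication state, and on vs off within each
# group: 95% HDIs, difference distributions, posterior Cohen's d, and
# credible-difference fractions (one-sided cutoff 97.5%).

library(sborg)

out <- "results/analysis"
draws_of <- function(nm) {
  tab <- read.csv(file.path(out, paste0("happiness_group_draws_", nm, ".csv")))
  as.list(tab[c("w0", "w1", "w2", "w3", "gamma")])
}

pairs <- list(icd_vs_nonicd_off = c("icd_off", "nonicd_off"),
              icd_vs_nonicd_on = c("icd_on", "nonicd_on"),
              nonicd_on_vs_off = c("nonicd_on", "nonicd_off"),
              icd_on_vs_off = c("icd_on", "icd_off"))

for (nm in names(pairs)) {
  p <- pairs[[nm]]
  cmp <- compare_cells(draws_of(p[1]), draws_of(p[2]))
  cat("\n==", nm, "(A =", p[1], ", B =", p[2], ") ==\n")
  print(cmp)
  write_table(cmp, file.path(out, paste0("comparison_", nm, ".csv")))
  if (any(cmp$credible))
    cat("credible differences:",
        paste(cmp$parameter[cmp$credible], collapse = ", "), "\n")
  else cat("no parameter clears the 97.5% credible cutoff\n")
}
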