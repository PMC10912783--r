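#!/usr/bin/env Rscript
# Stage 5 — descriptive evaluation and collation.
#
# Gamble-rate contrasts (rank-sum between groups, signed-rank within group)
# and the pooled model-fit r-squared per condition cell.

library(sborg)

out <- "results/analysis"
sessions <- read_sessions(file.path(out, "sessions.csv"))

rates <- gamble_rate_report(sessions)
write_table(rates$tests, file.path(out, "gamble_rate_tests.csv"))
cat("Gamble-rate contrasts:\n")
print(rates$tests, digits = 3)

r2_files <- list.files(out, pattern = "^fit_r2_.*\\.csv$", full.names = TRUE)
r2 <- do.call(rbind, lapply(r2_files, read.csv))
write_table(r2, file.path(out, "fit_r2_all.csv"))
cat("\nModel-fit r^2 per condition cell:\n")
print(r2, digits = 4)
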