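# Descriptive evaluation: gamble rates with nonparametric comparisons, and
# r-squared between actual and model-predicted ratings.

#' Per-session gamble rate
#'
#' Percentage of responded (non-timeout) trials on which the gamble was
#' chosen.
#'
#' @param session An `sborg_session`.
#' @return Percent in `[0, 100]`.
#' @export
gamble_rate <- function(session) {
  responded <- !is.na(session$choice) & session$choice != "timeout"
  if (!any(responded))
    stop("no responded trials; gamble rate undefined", call. = FALSE)
  100 * mean(session$choice[responded] == "gamble")
}

#' Nonparametric comparison of gamble rates
#'
#' Unpaired contrasts (between groups within a medication state) use the
#' Wilcoxon rank-sum test; paired contrasts (on vs off within a group, one
#' rate pair per subject) use the signed-rank test.  When every paired
#' difference is exactly zero the signed-rank statistic is undefined and the
#' p-value is reported as 1 (no evidence of any shift).
#'
#' @param rates_a,rates_b Per-session gamble rates (percent).
#' @param paired Use the signed-rank test on `rates_a - rates_b`.
#' @return Two-sided p-value.
#' @export
compare_gamble_rates <- function(rates_a, rates_b, paired = FALSE) {
  if (paired && length(rates_a) != length(rates_b))
    stop("paired comparison needs equal-length rate vectors", call. = FALSE)
  if (length(rates_a) < 2L || length(rates_b) < 2L)
    stop("need at least 2 rates per side", call. = FALSE)
  if (paired && all(rates_a == rates_b)) return(1)
  suppressWarnings(
    stats::wilcox.test(rates_a, rates_b, paired = paired)$p.value)
}

#' Squared correlation between actual and predicted ratings
#'
#' @param actual,predicted Equal-length numeric vectors (length >= 3) with
#'   nonzero variance.
#' @return Squared Pearson correlation (sign of the association discarded).
#' @export
fit_r2 <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  if (length(actual) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    stop("zero variance; r-squared undefined", call. = FALSE)
  stats::cor(actual, predicted)^2
}

#' Gamble-rate report for a cohort
#'
#' Per-session rates plus the standard contrasts: ICD vs non-ICD within each
#' medication state (rank-sum) and on vs off within each group (signed-rank,
#' paired by subject).
#'
#' @param cohort An `sborg_cohort` or list of sessions.
#' @return List with `rates` (per-session data frame) and `tests` (contrast,
#'   p-value).
#' @export
gamble_rate_report <- function(cohort) {
  sessions <- if (inherits(cohort, "sborg_cohort")) cohort$sessions else cohort
  rates <- do.call(rbind, lapply(sessions, function(s)
    data.frame(subject_id = s$subject_id[1L], group = s$group[1L],
               med_state = s$med_state[1L], gamble_rate = gamble_rate(s))))
  get <- function(g, m) rates$gamble_rate[rates$group == g &
                                            rates$med_state == m]
  paired_get <- function(g) {
    on <- rates[rates$group == g & rates$med_state == "on", ]
    off <- rates[rates$group == g & rates$med_state == "off", ]
    shared <- intersect(on$subject_id, off$subject_id)
    list(on = on$gamble_rate[match(shared, on$subject_id)],
         off = off$gamble_rate[match(shared, off$subject_id)])
  }
  tests <- list()
  add <- function(name, p) tests[[length(tests) + 1L]] <<-
    data.frame(contrast = name, p_value = p)
  for (m in c("off", "on")) {
    a <- get("ICD", m); b <- get("non-ICD", m)
    if (length(a) >= 2L && length(b) >= 2L)
      add(paste0("ICD_vs_nonICD_", m), compare_gamble_rates(a, b))
  }
  for (g in c("ICD", "non-ICD")) {
    pg <- paired_get(g)
    if (length(pg$on) >= 2L)
      add(paste0(sub("-", "", g), "_on_vs_off"),
          compare_gamble_rates(pg$on, pg$off, paired = TRUE))
  }
  list(rates = rates, tests = do.call(rbind, tests))
}

#' Model-fit evaluation for a fitted condition cell
#'
#' Pools the rated trials of every subject in the cell and reports the
#' squared correlation between actual and predicted ratings, plus
#' per-subject values.
#'
#' @param fit An `sborg_hfit`.
#' @param sessions The cell's sessions.
#' @return List with `r2` (pooled) and `per_subject` (data frame).
#' @export
evaluate_cell <- function(fit, sessions) {
  pred <- predict_from_fit(fit, sessions)
  per <- lapply(split(pred, pred$subject_id), function(d) {
    r2 <- tryCatch(fit_r2(d$actual, d$predicted), error = function(e) NA_real_)
    data.frame(subject_id = d$subject_id[1L], n_rated = nrow(d), r2 = r2)
  })
  list(r2 = fit_r2(pred$actual, pred$predicted),
       per_subject = do.call(rbind, unname(per)))
}
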