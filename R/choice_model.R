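# Trial-level gamble-choice model: per-participant logistic regression of
# the decision to gamble on the gamble's expected value, the certain amount,
# and the previous trial's subjective rating, with group-level one-sample
# t-tests over the per-subject coefficients.

#' Build the choice-model design table from a session
#'
#' One row per usable responded trial: the binary gamble decision, the
#' gamble's expected value (`EV_G`), the certain amount (`EV_CR`), and the
#' previous subjective rating (`SR_H_prev`).  Two modes for the previous
#' rating:
#' \describe{
#'   \item{`rated_only`}{rows only for responded trials whose immediately
#'     preceding trial carries a rating (the stricter reading).}
#'   \item{`locf`}{rows for every responded trial after the first rating,
#'     with the most recent rating carried forward.}
#' }
#' Trial 1 is never included.
#'
#' @param session An `sborg_session`.
#' @param prev_rating_mode `"rated_only"` (default) or `"locf"`.
#' @param standardize Standardize the session's ratings before use (default
#'   `TRUE`); set `FALSE` when ratings are already on the z-scale.
#' @return Data frame of class `sborg_choice_table` with columns
#'   `trial_index`, `gamble_chosen`, `EV_G`, `EV_CR`, `SR_H_prev`.  Empty
#'   (with a warning) when the session has no rated trials.
#' @export
build_choice_table <- function(session,
                               prev_rating_mode = c("rated_only", "locf"),
                               standardize = TRUE) {
  prev_rating_mode <- match.arg(prev_rating_mode)
  stopifnot(is.data.frame(session))
  ses <- session[order(session$trial_index), , drop = FALSE]
  rating <- ses$rating
  rated <- !is.na(rating)
  if (!any(rated)) {
    warning("session has no rated trials; empty choice table", call. = FALSE)
    out <- data.frame(trial_index = integer(), gamble_chosen = integer(),
                      EV_G = numeric(), EV_CR = numeric(),
                      SR_H_prev = numeric())
    class(out) <- c("sborg_choice_table", "data.frame")
    return(out)
  }
  if (standardize) rating[rated] <- zscore_ratings(rating[rated])
  responded <- !is.na(ses$choice) & ses$choice != "timeout"
  n <- nrow(ses)
  if (prev_rating_mode == "rated_only") {
    keep <- which(responded & seq_len(n) > 1L & c(FALSE, rated[-n]))
    prev <- rating[keep - 1L]
  } else {
    last_rated <- cummax(ifelse(rated, seq_len(n), 0L))
    prev_idx <- c(0L, last_rated[-n])   # most recent rating strictly before t
    keep <- which(responded & prev_idx > 0L)
    prev <- rating[prev_idx[keep]]
  }
  out <- data.frame(
    trial_index = ses$trial_index[keep],
    gamble_chosen = as.integer(ses$choice[keep] == "gamble"),
    EV_G = gamble_ev(ses$gamble_low[keep], ses$gamble_high[keep]),
    EV_CR = ses$certain_value[keep],
    SR_H_prev = prev)
  class(out) <- c("sborg_choice_table", "data.frame")
  out
}

#' Fit the logistic gamble-choice model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, log-likelihood tolerance 1e-8) of the gamble decision on
#' `EV_G`, `EV_CR`, and `SR_H_prev`.  Estimates whose magnitude exceeds
#' `max_abs_beta` raise a separation flag (quasi-complete separation at
#' small n) rather than being silently shrunk.
#'
#' @param rows A [build_choice_table()] result with at least 10 rows and
#'   both outcome classes present.
#' @param include_prev_rating Include the `SR_H_prev` term (default `TRUE`).
#' @param max_abs_beta Separation guard threshold (default 20).
#' @return An object of class `sborg_choice_fit`: list with `coef` (named
#'   `beta0..beta3`; `beta3` `NA` when the term is dropped or inestimable),
#'   `se`, `converged`, `separation`, `n`.
#' @export
fit_logistic_choice <- function(rows, include_prev_rating = TRUE,
                                max_abs_beta = 20) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) < 10L)
    stop("need at least 10 choice rows to fit", call. = FALSE)
  if (length(unique(rows$gamble_chosen)) < 2L)
    stop("single-class outcomes: cannot fit a choice model", call. = FALSE)
  form <- if (include_prev_rating)
    gamble_chosen ~ EV_G + EV_CR + SR_H_prev else gamble_chosen ~ EV_G + EV_CR
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = rows,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  nm <- c("beta0", "beta1", "beta2", "beta3")
  coef_out <- stats::setNames(rep(NA_real_, 4L), nm)
  se_out <- stats::setNames(rep(NA_real_, 4L), nm)
  map <- c("(Intercept)" = "beta0", EV_G = "beta1", EV_CR = "beta2",
           SR_H_prev = "beta3")
  for (term in names(map)) {
    if (term %in% names(cf) && !is.na(cf[[term]])) {
      coef_out[map[[term]]] <- cf[[term]]
      se_out[map[[term]]] <- se[[term]]
    }
  }
  separation <- sep_warned ||
    any(abs(coef_out) > max_abs_beta, na.rm = TRUE)
  if (separation)
    warning("separation flag: coefficient magnitude guard tripped",
            call. = FALSE)
  structure(list(coef = coef_out, se = se_out,
                 converged = fit$converged, separation = separation,
                 n = nrow(rows)),
            class = "sborg_choice_fit")
}

#' Fit the choice model to every session of a cohort
#'
#' @param sessions List of `sborg_session`s.
#' @param prev_rating_mode,standardize Passed to [build_choice_table()].
#' @param min_rows Sessions with fewer usable rows are skipped with a
#'   warning (default 10).
#' @param ... Passed to [fit_logistic_choice()].
#' @return Data frame: one row per fitted session with `subject_id`,
#'   `group`, `med_state`, `beta0..beta3`, `separation`, `converged`, `n`.
#' @export
fit_choice_cohort <- function(sessions, prev_rating_mode = "rated_only",
                              standardize = TRUE, min_rows = 10L, ...) {
  rows <- lapply(sessions, function(ses) {
    tab <- tryCatch(
      build_choice_table(ses, prev_rating_mode = prev_rating_mode,
                         standardize = standardize),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(tab) || nrow(tab) < min_rows ||
        length(unique(tab$gamble_chosen)) < 2L) {
      warning("skipping ", ses$subject_id[1L], " (", ses$med_state[1L],
              "): too few usable choice rows", call. = FALSE)
      return(NULL)
    }
    fit <- suppressWarnings(fit_logistic_choice(tab, ...))
    data.frame(subject_id = ses$subject_id[1L], group = ses$group[1L],
               med_state = ses$med_state[1L],
               beta0 = fit$coef[["beta0"]], beta1 = fit$coef[["beta1"]],
               beta2 = fit$coef[["beta2"]], beta3 = fit$coef[["beta3"]],
               separation = fit$separation, converged = fit$converged,
               n = fit$n)
  })
  do.call(rbind, rows)
}

#' Group-level test of one choice coefficient
#'
#' Mean of the per-subject coefficients, with a two-sided one-sample t-test
#' against zero and a t-based 95% confidence interval (n - 1 degrees of
#' freedom).
#'
#' @param estimates Per-subject coefficient estimates (length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame row: `estimate`, `ci_low`, `ci_high`, `t_statistic`,
#'   `p_value`, `n`, `zero_variance` (flag; t and p are `NA` when all
#'   estimates coincide).
#' @export
group_coefficient_test <- function(estimates, conf_level = 0.95) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) < 2L)
    stop("need at least 2 subject-level estimates", call. = FALSE)
  if (stats::sd(estimates) == 0) {
    warning("zero variance across subjects; t-statistic undefined",
            call. = FALSE)
    return(data.frame(estimate = mean(estimates),
                      ci_low = mean(estimates), ci_high = mean(estimates),
                      t_statistic = NA_real_, p_value = NA_real_,
                      n = length(estimates), zero_variance = TRUE))
  }
  tt <- stats::t.test(estimates, mu = 0, conf.level = conf_level)
  data.frame(estimate = unname(tt$estimate),
             ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L],
             t_statistic = unname(tt$statistic),
             p_value = tt$p.value, n = length(estimates),
             zero_variance = FALSE)
}

#' Group summary of per-subject choice fits
#'
#' Mirrors the choice-model report layout: one row per coefficient
#' (Baseline, Gamble EV, Certain Reward EV, previous subjective rating) per
#' condition cell present in the table.
#'
#' @param coef_table [fit_choice_cohort()] output.
#' @return Data frame with `group`, `med_state`, `coefficient`, and the
#'   [group_coefficient_test()] columns.
#' @export
choice_group_summary <- function(coef_table) {
  stopifnot(is.data.frame(coef_table))
  cells <- unique(coef_table[c("group", "med_state")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- coef_table[coef_table$group == cells$group[i] &
                        coef_table$med_state == cells$med_state[i], ]
    for (b in paste0("beta", 0:3)) {
      est <- sub[[b]]
      if (sum(!is.na(est)) < 2L) next
      res <- group_coefficient_test(est)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(group = cells$group[i],
                         med_state = cells$med_state[i], coefficient = b),
              res)
    }
  }
  do.call(rbind, rows)
}
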