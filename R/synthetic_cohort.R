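# Synthetic cohorts of task-performing agents.
#
# Choices follow the logistic gamble-choice rule
#   logit P(gamble on trial t) = b0 + b1 EV_G(t) + b2 EV_CR(t) + b3 SR_H(t-1)
# and emitted ratings follow the momentary-happiness model plus Gaussian
# noise, with subject-level parameters drawn around group-level means.  A
# ground-truth manifest accompanies every cohort for recovery testing.

#' Choice-model parameters
#'
#' @param beta0 Baseline log-odds of gambling.
#' @param beta1 Weight per dollar of gamble expected value.
#' @param beta2 Weight per dollar of certain-reward value.
#' @param beta3 Weight on the previous subjective rating (z-units).
#' @return An object of class `sborg_choice_params`.
#' @export
choice_params <- function(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0) {
  stopifnot(is.finite(c(beta0, beta1, beta2, beta3)))
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3),
            class = "sborg_choice_params")
}

#' Group specification for cohort simulation
#'
#' Defines one condition cell (group label x medication state): how many
#' subjects, and the group-level means and standard deviations the
#' subject-level parameters are drawn around.  The forgetting factor `gamma`
#' is specified on its natural `[0, 1]` scale but heterogeneity acts on the
#' unconstrained log-odds scale (subject draws stay in `[0, 1]` without
#' truncation).
#'
#' @param label Group label, `"ICD"` or `"non-ICD"`.
#' @param med_state Medication state, `"on"` or `"off"`.
#' @param n_subjects Number of subjects in the cell.
#' @param means Named list of group-level means: `w0..w3`, `gamma` (natural
#'   scale), `rating_noise_sd`, `beta0..beta3`.
#' @param sds Named list of group-level standard deviations for `w0..w3`,
#'   `gamma` (on the unconstrained scale), `rating_noise_sd`, `beta0..beta3`.
#'   All must be nonnegative; zero gives a homogeneous group.
#' @param timeout_prob Per-trial probability of a response timeout
#'   (default 0.03, matching the task's observed rarity of timeouts).
#' @return An object of class `sborg_group_spec`.
#' @export
group_spec <- function(label = c("ICD", "non-ICD"), med_state = c("off", "on"),
                       n_subjects,
                       means = list(w0 = 0, w1 = 0.2, w2 = 0.2, w3 = 0.4,
                                    gamma = 0.15, rating_noise_sd = 0.5,
                                    beta0 = 0, beta1 = 2, beta2 = -2,
                                    beta3 = 0),
                       sds = default_group_sds(), timeout_prob = 0.03) {
  label <- match.arg(label)
  med_state <- match.arg(med_state)
  stopifnot(n_subjects >= 1, n_subjects == round(n_subjects))
  need <- c("w0", "w1", "w2", "w3", "gamma", "rating_noise_sd",
            paste0("beta", 0:3))
  if (!all(need %in% names(means)))
    stop("`means` must name: ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(need %in% names(sds)))
    stop("`sds` must name: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(unlist(sds[need]) < 0))
    stop("all `sds` must be nonnegative", call. = FALSE)
  if (means$gamma <= 0 || means$gamma >= 1)
    stop("`means$gamma` must lie strictly inside (0, 1)", call. = FALSE)
  if (timeout_prob < 0 || timeout_prob > 1)
    stop("`timeout_prob` must be a probability", call. = FALSE)
  structure(list(label = label, med_state = med_state,
                 n_subjects = as.integer(n_subjects),
                 means = means[need], sds = sds[need],
                 timeout_prob = timeout_prob),
            class = "sborg_group_spec")
}

#' Default group-level dispersions
#'
#' Weakly heterogeneous defaults resembling the scatter of individual
#' parameter means around their group means: 0.05 for the happiness weights,
#' 0.5 for unconstrained gamma, 0.3 for the choice betas, 0 for the rating
#' noise scale.
#'
#' @return Named list of standard deviations.
#' @export
default_group_sds <- function() {
  list(w0 = 0.05, w1 = 0.05, w2 = 0.05, w3 = 0.05, gamma = 0.5,
       rating_noise_sd = 0, beta0 = 0.3, beta1 = 0.3, beta2 = 0.3,
       beta3 = 0.3)
}

#' Shipped condition-cell presets
#'
#' Four [group_spec()]s (ICD/non-ICD x on/off medication) whose group-level
#' means are the reported group estimates of the happiness and choice models
#' for each cell: 18 ICD and 12 non-ICD subjects.  The previous-rating choice
#' weight defaults to 0 (it was not a significant predictor in any cell).
#'
#' @param n_icd,n_nonicd Subjects per group (defaults 18 and 12).
#' @param sds Group-level dispersions, see [default_group_sds()].
#' @param timeout_prob Per-trial timeout probability.
#' @return Named list of four `sborg_group_spec`s:
#'   `icd_off`, `nonicd_off`, `icd_on`, `nonicd_on`.
#' @export
sborg_presets <- function(n_icd = 18L, n_nonicd = 12L,
                          sds = default_group_sds(), timeout_prob = 0.03) {
  cell <- function(label, med, n, w, g, b) {
    group_spec(label, med, n,
               means = list(w0 = w[1], w1 = w[2], w2 = w[3], w3 = w[4],
                            gamma = g, rating_noise_sd = 0.5,
                            beta0 = b[1], beta1 = b[2], beta2 = b[3],
                            beta3 = 0),
               sds = sds, timeout_prob = timeout_prob)
  }
  list(
    icd_off = cell("ICD", "off", n_icd,
                   c(-0.6243, 0.1372, 0.1058, 0.3298), 0.1754,
                   c(0.0223, 1.9517, -1.8869)),
    nonicd_off = cell("non-ICD", "off", n_nonicd,
                      c(-1.1564, 0.2418, 0.2261, 0.4602), 0.1414,
                      c(-0.2368, 2.3155, -2.1320)),
    icd_on = cell("ICD", "on", n_icd,
                  c(-0.8422, 0.1902, 0.1657, 0.3459), 0.1434,
                  c(-0.1182, 2.2426, -2.0518)),
    nonicd_on = cell("non-ICD", "on", n_nonicd,
                     c(-1.0175, 0.2231, 0.1914, 0.4453), 0.165,
                     c(-0.2583, 2.1248, -1.9846)))
}

#' Draw one agent's parameters from a group specification
#'
#' Each parameter is drawn from a normal law with the group's mean and
#' standard deviation.  `gamma` is drawn on the unconstrained log-odds scale
#' and mapped back through the standard logistic, so draws always lie in
#' `[0, 1]`.  A nonpositive rating-noise draw is replaced by 0.01 to keep
#' the scale positive.
#'
#' @param group An [group_spec()].
#' @param seed Optional integer seed.
#' @return An object of class `sborg_agent` with elements `happiness`
#'   ([happiness_params()]), `choice` ([choice_params()]), and
#'   `timeout_prob`.
#' @export
draw_agent <- function(group, seed = NULL) {
  stopifnot(inherits(group, "sborg_group_spec"))
  local_seed(seed, {
    m <- group$means; s <- group$sds
    w <- stats::rnorm(4, unlist(m[c("w0", "w1", "w2", "w3")]),
                      unlist(s[c("w0", "w1", "w2", "w3")]))
    g <- stats::plogis(stats::rnorm(1, stats::qlogis(m$gamma), s$gamma))
    noise <- stats::rnorm(1, m$rating_noise_sd, s$rating_noise_sd)
    if (noise <= 0) noise <- 0.01
    b <- stats::rnorm(4, unlist(m[paste0("beta", 0:3)]),
                      unlist(s[paste0("beta", 0:3)]))
    structure(list(
      happiness = happiness_params(w[1], w[2], w[3], w[4], g, noise),
      choice = choice_params(b[1], b[2], b[3], b[4]),
      timeout_prob = group$timeout_prob),
      class = "sborg_agent")
  })
}

#' Simulate one session of an agent performing the task
#'
#' Walks the schedule trial by trial.  With probability `timeout_prob` a
#' trial times out (no choice, outcome, or rating).  Otherwise the gamble is
#' chosen with the logistic choice probability driven by the gamble EV, the
#' certain value, and the last emitted rating carried forward (0 before the
#' first rating); gamble outcomes resolve 50/50.  Latent happiness follows
#' the momentary-happiness model over the responded-trial history, and on
#' prompted trials an emitted rating equals latent happiness plus Gaussian
#' noise.  With `rating_scale = "slider"`, emitted ratings are mapped
#' affinely (2 slider units per z-unit) and rounded onto the -4..+4 integer
#' grid for I/O realism.
#'
#' @param agent [draw_agent()] output.
#' @param schedule [generate_schedule()] output.
#' @param seed Optional integer seed.
#' @param subject_id,group,med_state Labels stamped on every row.
#' @param rating_scale `"z"` (default: ratings emitted on the model scale) or
#'   `"slider"`.
#' @return A data frame of class `sborg_session`: the schedule columns plus
#'   `subject_id`, `group`, `med_state`, `choice` (`"certain"`, `"gamble"`,
#'   `"timeout"`), `outcome` (dollars, `NA` on timeouts), `rating` (`NA`
#'   when absent).
#' @export
simulate_session <- function(agent, schedule, seed = NULL,
                             subject_id = "S1", group = "ICD",
                             med_state = "off", rating_scale = c("z", "slider")) {
  stopifnot(inherits(agent, "sborg_agent"), inherits(schedule, "sborg_schedule"),
            nrow(schedule) >= 1L)
  rating_scale <- match.arg(rating_scale)
  hp <- agent$happiness; cp <- agent$choice
  local_seed(seed, {
    n <- nrow(schedule)
    choice <- character(n); outcome <- rep(NA_real_, n)
    rating <- rep(NA_real_, n)
    sCR <- sEV <- sRPE <- 0   # decayed sums over responded history
    sr_prev <- 0              # last emitted rating (z-scale), 0 before first
    for (i in seq_len(n)) {
      if (stats::runif(1) < agent$timeout_prob) {
        choice[i] <- "timeout"
        next
      }
      ev <- gamble_ev(schedule$gamble_low[i], schedule$gamble_high[i])
      p_gamble <- stats::plogis(cp$beta0 + cp$beta1 * ev +
                                  cp$beta2 * schedule$certain_value[i] +
                                  cp$beta3 * sr_prev)
      take_gamble <- stats::runif(1) < p_gamble
      if (take_gamble) {
        choice[i] <- "gamble"
        outcome[i] <- if (stats::runif(1) < 0.5) schedule$gamble_high[i]
                      else schedule$gamble_low[i]
        sCR <- hp$gamma * sCR
        sEV <- hp$gamma * sEV + ev
        sRPE <- hp$gamma * sRPE + (outcome[i] - ev)
      } else {
        choice[i] <- "certain"
        outcome[i] <- schedule$certain_value[i]
        sCR <- hp$gamma * sCR + schedule$certain_value[i]
        sEV <- hp$gamma * sEV
        sRPE <- hp$gamma * sRPE
      }
      if (schedule$rating_prompt[i]) {
        latent <- hp$w0 + hp$w1 * sCR + hp$w2 * sEV + hp$w3 * sRPE
        r <- latent + stats::rnorm(1, 0, hp$rating_noise_sd)
        if (rating_scale == "slider")
          r <- pmin(pmax(round(2 * r), -4), 4)
        rating[i] <- r
        sr_prev <- if (rating_scale == "slider") r / 2 else r
      }
    }
    out <- cbind(
      data.frame(subject_id = subject_id, group = group,
                 med_state = med_state),
      as.data.frame(schedule),
      data.frame(choice = choice, outcome = outcome, rating = rating))
    class(out) <- c("sborg_session", "data.frame")
    out
  })
}

#' Simulate a full cohort across condition cells
#'
#' One session per subject per group specification, each with its own freshly
#' drawn schedule and agent.  Fully reproducible from `seed`; a ground-truth
#' manifest records every subject-session's generative parameters for
#' recovery testing.
#'
#' @param groups List of [group_spec()]s (e.g. [sborg_presets()]).  Subjects
#'   appearing in both an on and an off cell share ids when the two cells
#'   carry the same `label`.
#' @param task [task_config()] shared by all sessions.
#' @param seed Integer seed (required: cohorts are reproducibility-critical).
#' @param rating_scale Passed to [simulate_session()].
#' @return An object of class `sborg_cohort`: list with `sessions` (list of
#'   `sborg_session`) and `manifest` (one row per session: labels, seed, and
#'   all true parameters).
#' @export
simulate_cohort <- function(groups, task = task_config(), seed,
                            rating_scale = "z") {
  if (missing(seed) || is.null(seed))
    stop("`seed` is required for cohort simulation", call. = FALSE)
  if (length(groups) == 0L)
    return(structure(list(sessions = list(),
                          manifest = empty_manifest()),
                     class = "sborg_cohort"))
  stopifnot(all(vapply(groups, inherits, logical(1), "sborg_group_spec")))
  local_seed(seed, {
    sessions <- list()
    manifest <- list()
    for (g in groups) {
      sub_seeds <- draw_subseeds(2L * g$n_subjects)
      for (k in seq_len(g$n_subjects)) {
        sid <- sprintf("%s-%02d", sub("non-ICD", "NICD", g$label), k)
        agent <- draw_agent(g, seed = sub_seeds[2L * k - 1L])
        sched <- generate_schedule(
          task_config(n_trials = task$n_trials,
                      rating_prob = task$rating_prob,
                      certain_values = task$certain_values,
                      gamble_values = task$gamble_values,
                      dominated_fraction = task$dominated_fraction,
                      time_limit_rate = task$time_limit_rate,
                      session_minutes = task$session_minutes,
                      seed = sub_seeds[2L * k]))
        ses <- simulate_session(agent, sched, seed = sub_seeds[2L * k],
                                subject_id = sid, group = g$label,
                                med_state = g$med_state,
                                rating_scale = rating_scale)
        sessions[[length(sessions) + 1L]] <- ses
        hp <- agent$happiness; cp <- agent$choice
        manifest[[length(manifest) + 1L]] <- data.frame(
          subject_id = sid, group = g$label, med_state = g$med_state,
          seed = sub_seeds[2L * k],
          w0 = hp$w0, w1 = hp$w1, w2 = hp$w2, w3 = hp$w3,
          gamma = hp$gamma, rating_noise_sd = hp$rating_noise_sd,
          beta0 = cp$beta0, beta1 = cp$beta1, beta2 = cp$beta2,
          beta3 = cp$beta3, timeout_prob = agent$timeout_prob)
      }
    }
    structure(list(sessions = sessions,
                   manifest = do.call(rbind, manifest)),
              class = "sborg_cohort")
  })
}

empty_manifest <- function() {
  data.frame(subject_id = character(), group = character(),
             med_state = character(), seed = integer(),
             w0 = numeric(), w1 = numeric(), w2 = numeric(), w3 = numeric(),
             gamma = numeric(), rating_noise_sd = numeric(),
             beta0 = numeric(), beta1 = numeric(), beta2 = numeric(),
             beta3 = numeric(), timeout_prob = numeric())
}

#' Select a cohort's sessions by condition cell
#'
#' @param cohort An `sborg_cohort` (or plain list of sessions).
#' @param group,med_state Cell labels; `NULL` matches everything.
#' @return List of `sborg_session`s.
#' @export
cell_sessions <- function(cohort, group = NULL, med_state = NULL) {
  sessions <- if (inherits(cohort, "sborg_cohort")) cohort$sessions else cohort
  keep <- vapply(sessions, function(s) {
    (is.null(group) || s$group[1] == group) &&
      (is.null(med_state) || s$med_state[1] == med_state)
  }, logical(1))
  sessions[keep]
}

#' @export
print.sborg_cohort <- function(x, ...) {
  cat("SBORG synthetic cohort:", length(x$sessions), "sessions\n")
  if (nrow(x$manifest))
    print(table(x$manifest$group, x$manifest$med_state))
  invisible(x)
}
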