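# Sure-Bet-or-Gamble (SBORG) task: trial structure and schedule generation.
#
# Each trial offers a certain reward ($1-$6) against a two-outcome gamble
# ($0-$6 each, 50/50).  A random third of trials prompt a feeling rating on a
# -4..+4 slider, and each trial carries a response time limit drawn from a
# Poisson distribution (lambda = 6 s).

#' Task configuration for the Sure-Bet-or-Gamble task
#'
#' Bundles the design constants of the SBORG task: trial count, rating-prompt
#' probability, the integer dollar grids for the certain option and the gamble
#' outcomes, the fraction of dominated "control" trials, and the mean of the
#' Poisson response-time-limit distribution.
#'
#' @param n_trials Number of trials in a session (default 208, the average
#'   session length of the task).
#' @param rating_prob Probability that a trial prompts a subjective-feeling
#'   rating (default 0.33).
#' @param certain_values Integer dollar amounts the certain option is drawn
#'   from; must lie in 1..6.
#' @param gamble_values Integer dollar amounts each gamble outcome is drawn
#'   from; must lie in 0..6.
#' @param dominated_fraction Probability that a trial is a dominated control
#'   trial (one option weakly better than the other in every outcome).
#' @param time_limit_rate Mean (lambda, seconds) of the Poisson response time
#'   limit distribution (default 6).
#' @param session_minutes Nominal session duration in minutes; informational
#'   only (sessions terminate after `n_trials` trials).
#' @param seed Integer seed making [generate_schedule()] deterministic, or
#'   `NULL` to use the current RNG state.
#' @return An object of class `sborg_task_config` (a validated list).
#' @seealso [generate_schedule()]
#' @export
task_config <- function(n_trials = 208L, rating_prob = 0.33,
                        certain_values = 1:6, gamble_values = 0:6,
                        dominated_fraction = 0.2, time_limit_rate = 6,
                        session_minutes = 30, seed = NULL) {
  stopifnot(length(n_trials) == 1L, n_trials >= 1, n_trials == round(n_trials))
  if (!is.numeric(rating_prob) || rating_prob < 0 || rating_prob > 1)
    stop("`rating_prob` must be a probability in [0, 1]", call. = FALSE)
  certain_values <- as.integer(certain_values)
  gamble_values <- as.integer(gamble_values)
  if (length(certain_values) == 0L || length(gamble_values) == 0L)
    stop("value sets must be nonempty", call. = FALSE)
  if (!all(certain_values %in% 1:6))
    stop("`certain_values` must be a subset of 1..6 dollars", call. = FALSE)
  if (!all(gamble_values %in% 0:6))
    stop("`gamble_values` must be a subset of 0..6 dollars", call. = FALSE)
  if (dominated_fraction < 0 || dominated_fraction > 1)
    stop("`dominated_fraction` must be in [0, 1]", call. = FALSE)
  if (time_limit_rate < 0)
    stop("`time_limit_rate` must be nonnegative", call. = FALSE)
  stopifnot(session_minutes > 0)
  structure(
    list(n_trials = as.integer(n_trials), rating_prob = rating_prob,
         certain_values = certain_values, gamble_values = gamble_values,
         dominated_fraction = dominated_fraction,
         time_limit_rate = time_limit_rate,
         session_minutes = session_minutes,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sborg_task_config")
}

#' Expected value of a 50/50 two-outcome gamble
#'
#' @param gamble_low,gamble_high Nonnegative dollar amounts of the two
#'   equiprobable outcomes.  Vectorized.
#' @return `0.5 * (gamble_low + gamble_high)`, in dollars.
#' @examples
#' gamble_ev(0, 6)  # 3
#' @export
gamble_ev <- function(gamble_low, gamble_high) {
  if (any(gamble_low < 0) || any(gamble_high < 0))
    stop("gamble outcomes must be nonnegative", call. = FALSE)
  0.5 * (gamble_low + gamble_high)
}

#' Classify a trial by option dominance
#'
#' A trial is `dominated_certain` when the certain amount is at least the
#' larger gamble outcome, `dominated_gamble` when it is at most the smaller
#' one, and `conflict` otherwise.  Ties count as dominated: weak dominance
#' still makes one option rationally no worse than the other.
#'
#' @param certain_value Certain-option dollar amount.  Vectorized.
#' @param gamble_low,gamble_high Gamble outcomes, `gamble_low <= gamble_high`.
#' @return Character vector over `{"dominated_certain", "dominated_gamble",
#'   "conflict"}`.
#' @export
classify_trial <- function(certain_value, gamble_low, gamble_high) {
  if (any(gamble_low > gamble_high))
    stop("`gamble_low` must not exceed `gamble_high`", call. = FALSE)
  if (any(certain_value < 0) || any(gamble_low < 0))
    stop("values must be nonnegative", call. = FALSE)
  ifelse(certain_value >= gamble_high, "dominated_certain",
         ifelse(certain_value <= gamble_low, "dominated_gamble", "conflict"))
}

#' Draw response time limits
#'
#' Time limits are integer seconds drawn from a Poisson distribution, matching
#' the task's randomized per-trial response deadline.
#'
#' @param n Number of draws.
#' @param rate Poisson mean in seconds (default 6).
#' @return Integer vector of `n` nonnegative time limits.
#' @export
draw_time_limit <- function(n, rate = 6) {
  if (rate < 0) stop("`rate` must be nonnegative", call. = FALSE)
  stats::rpois(n, rate)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream;
# seed = NULL runs in the ambient stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive reproducible sub-seeds from an already-seeded stream.
draw_subseeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

#' Generate a trial schedule
#'
#' Draws `n_trials` trial specifications: with probability
#' `dominated_fraction` a dominated control trial (dominated-certain or
#' dominated-gamble with equal probability), otherwise a conflict trial where
#' the certain amount lies strictly between the gamble outcomes.  Rating
#' prompts are independent Bernoulli(`rating_prob`) draws; time limits are
#' Poisson(`time_limit_rate`).  Deterministic given `config$seed`.
#'
#' @param config An [task_config()] object.
#' @return A data frame of class `sborg_schedule` with columns `trial_index`,
#'   `certain_value`, `gamble_low`, `gamble_high`, `rating_prompt`,
#'   `time_limit`, `dominance_class`.
#' @export
generate_schedule <- function(config = task_config()) {
  stopifnot(inherits(config, "sborg_task_config"))
  local_seed(config$seed, {
    n <- config$n_trials
    target <- ifelse(stats::runif(n) < config$dominated_fraction,
                     ifelse(stats::runif(n) < 0.5,
                            "dominated_certain", "dominated_gamble"),
                     "conflict")
    cv <- gl <- gh <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        v <- sample(config$certain_values, 1L)
        g <- sort(sample(config$gamble_values, 2L, replace = TRUE))
        if (classify_trial(v, g[1L], g[2L]) == target[i]) break
      }
      cv[i] <- v; gl[i] <- g[1L]; gh[i] <- g[2L]
    }
    out <- data.frame(
      trial_index = seq_len(n),
      certain_value = cv, gamble_low = gl, gamble_high = gh,
      rating_prompt = stats::runif(n) < config$rating_prob,
      time_limit = draw_time_limit(n, config$time_limit_rate),
      dominance_class = target)
    class(out) <- c("sborg_schedule", "data.frame")
    out
  })
}

#' Read or write a trial schedule as delimited text
#'
#' Schedules round-trip through a comma-delimited file with a header row.
#'
#' @param schedule An `sborg_schedule` data frame.
#' @param path File path.
#' @return `read_schedule()` returns an `sborg_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "sborg_schedule"))
  utils::write.csv(schedule, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "certain_value", "gamble_low", "gamble_high",
            "rating_prompt", "time_limit", "dominance_class")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("schedule file misses columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out$rating_prompt <- as.logical(out$rating_prompt)
  chk <- classify_trial(out$certain_value, out$gamble_low, out$gamble_high)
  bad <- which(chk != out$dominance_class)
  if (length(bad))
    stop("dominance_class inconsistent with option values at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  class(out) <- c("sborg_schedule", "data.frame")
  out
}
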