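# Momentary-happiness model: trial-history regressors, exponentially
# forgetting decayed sums, forward prediction, and rating standardization.
#
# The model expresses the feeling rating after trial t as
#   Happiness(t) = w0 + w1 * sum_j g^(t-j) CR_j
#                     + w2 * sum_j g^(t-j) EV_j
#                     + w3 * sum_j g^(t-j) RPE_j,    j = 1..t,
# where CR_j is the certain amount when the certain option was chosen on
# trial j (else 0), EV_j the chosen gamble's expected value (else 0), RPE_j
# the obtained gamble outcome minus EV_j (else 0), and g in [0,1] a
# forgetting factor discounting older trials.

#' Happiness-model parameters
#'
#' @param w0 Intercept (baseline feeling, z-units).
#' @param w1 Weight on the decayed sum of chosen certain rewards (z-units per
#'   dollar).
#' @param w2 Weight on the decayed sum of chosen-gamble expected values.
#' @param w3 Weight on the decayed sum of reward prediction errors.
#' @param gamma Forgetting factor in `[0, 1]`; 0 means only the current trial
#'   matters, 1 means no forgetting.
#' @param rating_noise_sd Standard deviation (z-units) of Gaussian rating
#'   noise around the latent happiness; must be positive.
#' @return An object of class `sborg_happiness_params`.
#' @export
happiness_params <- function(w0 = 0, w1 = 0, w2 = 0, w3 = 0, gamma = 0.5,
                             rating_noise_sd = 0.5) {
  if (gamma < 0 || gamma > 1) stop("`gamma` must be in [0, 1]", call. = FALSE)
  if (rating_noise_sd <= 0)
    stop("`rating_noise_sd` must be positive", call. = FALSE)
  structure(list(w0 = w0, w1 = w1, w2 = w2, w3 = w3, gamma = gamma,
                 rating_noise_sd = rating_noise_sd),
            class = "sborg_happiness_params")
}

#' Build happiness-model regressors from a session
#'
#' Drops timeout trials, compacts indices, and computes the per-trial triple
#' (CR, EV, RPE): a certain choice contributes its dollar amount to CR only; a
#' gamble choice contributes its expected value to EV and `outcome - EV` to
#' RPE.  Exactly one of CR and EV is nonzero on every responded trial.
#'
#' @param session An `sborg_session` data frame (see [simulate_session()] /
#'   [read_sessions()]).
#' @return A data frame of class `sborg_regressors` with columns
#'   `trial_index` (original index), `CR`, `EV`, `RPE`, `rated` (rating
#'   present), `rating`.
#' @export
build_regressors <- function(session) {
  stopifnot(is.data.frame(session))
  resp <- session[!is.na(session$choice) & session$choice != "timeout", ,
                  drop = FALSE]
  if (any(is.na(resp$outcome)))
    stop("missing outcome on responded trial(s): index ",
         paste(utils::head(resp$trial_index[is.na(resp$outcome)], 5L),
               collapse = ", "), call. = FALSE)
  certain <- resp$choice == "certain"
  ev <- gamble_ev(resp$gamble_low, resp$gamble_high)
  out <- data.frame(
    trial_index = resp$trial_index,
    CR = ifelse(certain, resp$certain_value, 0),
    EV = ifelse(certain, 0, ev),
    RPE = ifelse(certain, 0, resp$outcome - ev),
    rated = !is.na(resp$rating),
    rating = resp$rating)
  class(out) <- c("sborg_regressors", "data.frame")
  out
}

#' Exponentially decayed running sum
#'
#' Computes `S_t = sum_{j=1..t} gamma^(t-j) x_j`, equivalently the recursion
#' `S_t = gamma * S_{t-1} + x_t`.  `0^0` is taken as 1, so `gamma = 0`
#' returns the current value alone.
#'
#' @param x Numeric series.
#' @param gamma Forgetting factor in `[0, 1]`.
#' @param t Trial index; `NULL` (default) returns the whole running series.
#' @return `S_t` (scalar) or the vector `S_1..S_n`.
#' @export
decayed_sum <- function(x, gamma, t = NULL) {
  if (gamma < 0 || gamma > 1) stop("`gamma` must be in [0, 1]", call. = FALSE)
  s <- as.numeric(stats::filter(x, gamma, method = "recursive"))
  if (is.null(t)) return(s)
  if (t < 1 || t > length(x)) stop("`t` out of range", call. = FALSE)
  s[t]
}

#' Forward happiness prediction
#'
#' Evaluates the momentary-happiness model on a regressor series: intercept
#' plus the weighted decayed sums of CR, EV, and RPE up to each trial.
#'
#' @param params [happiness_params()].
#' @param regressors [build_regressors()] output (or any data frame with
#'   `CR`, `EV`, `RPE` columns).
#' @param t Trial index; `NULL` returns predictions for every trial.
#' @return Predicted happiness in z-units (scalar or vector).
#' @export
predict_happiness <- function(params, regressors, t = NULL) {
  stopifnot(inherits(params, "sborg_happiness_params"))
  h <- params$w0 +
    params$w1 * decayed_sum(regressors$CR, params$gamma) +
    params$w2 * decayed_sum(regressors$EV, params$gamma) +
    params$w3 * decayed_sum(regressors$RPE, params$gamma)
  if (is.null(t)) return(h)
  if (t < 1 || t > nrow(regressors)) stop("`t` out of range", call. = FALSE)
  h[t]
}

#' Standardize ratings per participant
#'
#' Centers and scales to sample mean 0 and sample standard deviation 1
#' (denominator n - 1).  Constant ratings carry no usable variance; such
#' sessions are excluded from fitting upstream.
#'
#' @param ratings Numeric vector of raw ratings (at least two distinct
#'   values).
#' @return Standardized ratings.
#' @export
zscore_ratings <- function(ratings) {
  ratings <- ratings[!is.na(ratings)]
  if (length(ratings) < 2L)
    stop("need at least two ratings to standardize", call. = FALSE)
  s <- stats::sd(ratings)
  if (s == 0)
    stop("degenerate ratings: all values identical, zero variance",
         call. = FALSE)
  (ratings - mean(ratings)) / s
}
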