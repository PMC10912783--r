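# Hierarchical Bayesian fit of the momentary-happiness model.
#
# One condition cell (group x medication state) at a time: individual-level
# weights and forgetting factors are drawn around group-level means
# (non-centered parameterization), the forgetting factor is sampled on the
# unconstrained log-odds scale and reported through the logistic map, and
# observed standardized ratings follow a Gaussian observation model with a
# per-subject noise scale.  Sampling is MCMC via JAGS with fully seeded
# chains.

#' Prior configuration for the hierarchical happiness fit
#'
#' Weakly informative priors on the standardized-rating scale: group means
#' (weights and unconstrained gamma) are normal, group standard deviations
#' and the per-subject rating-noise scale are half-normal.
#'
#' @param mean_loc,mean_scale Location and scale of the normal prior on every
#'   group-level mean (defaults 0 and 1).
#' @param sd_scale Scale of the half-normal prior on group-level standard
#'   deviations (default 0.2).
#' @param noise_scale Scale of the half-normal prior on per-subject rating
#'   noise (default 1).
#' @return An object of class `sborg_prior_config`.
#' @export
prior_config <- function(mean_loc = 0, mean_scale = 1, sd_scale = 0.2,
                         noise_scale = 1) {
  stopifnot(mean_scale > 0, sd_scale > 0, noise_scale > 0)
  structure(list(mean_loc = mean_loc, mean_scale = mean_scale,
                 sd_scale = sd_scale, noise_scale = noise_scale),
            class = "sborg_prior_config")
}

happiness_model_string <- "
model {
  for (p in 1:4) {
    mu_w[p] ~ dnorm(prior_mean_loc, pow(prior_mean_scale, -2))
    sigma_w[p] ~ dnorm(0, pow(prior_sd_scale, -2)) T(0,)
  }
  mu_g ~ dnorm(prior_mean_loc, pow(prior_mean_scale, -2))
  sigma_g ~ dnorm(0, pow(prior_sd_scale, -2)) T(0,)
  for (s in 1:S) {
    for (p in 1:4) {
      zw[s, p] ~ dnorm(0, 1)
      w[s, p] <- mu_w[p] + sigma_w[p] * zw[s, p]
    }
    zg[s] ~ dnorm(0, 1)
    gam[s] <- ilogit(mu_g + sigma_g * zg[s])
    sigma_eps[s] ~ dnorm(0, pow(prior_noise_scale, -2)) T(0,)
    SCR[first[s]] <- CR[first[s]]
    SEV[first[s]] <- EV[first[s]]
    SRPE[first[s]] <- RPE[first[s]]
    for (t in (first[s] + 1):last[s]) {
      SCR[t] <- gam[s] * SCR[t - 1] + CR[t]
      SEV[t] <- gam[s] * SEV[t - 1] + EV[t]
      SRPE[t] <- gam[s] * SRPE[t - 1] + RPE[t]
    }
  }
  for (i in 1:Nobs) {
    mu_r[i] <- w[rsubj[i], 1] + w[rsubj[i], 2] * SCR[rtrial[i]] +
               w[rsubj[i], 3] * SEV[rtrial[i]] + w[rsubj[i], 4] * SRPE[rtrial[i]]
    robs[i] ~ dnorm(mu_r[i], pow(sigma_eps[rsubj[i]], -2))
  }
  gamma_group <- ilogit(mu_g)
}"

#' Fit the happiness model hierarchically to one condition cell
#'
#' Builds the trial-history regressors per subject, standardizes ratings when
#' requested, and samples the joint posterior of group-level means and
#' standard deviations plus individual-level parameters by MCMC (JAGS,
#' seeded chains, non-centered individual effects).  Subjects with fewer
#' than `min_rated` usable ratings or degenerate (constant) ratings are
#' excluded with a warning.  Convergence is checked by split R-hat; values
#' above 1.05 are flagged with a warning, not fatal.
#'
#' @param sessions List of `sborg_session` data frames from one condition
#'   cell (at least 2 usable subjects).
#' @param priors [prior_config()].
#' @param chains,adapt,warmup,iter MCMC settings: number of chains, adaptation
#'   steps, burn-in, and retained iterations per chain (defaults 4 chains,
#'   1000 warmup, 1000 retained).
#' @param seed Integer seed; every chain's RNG is derived from it.
#' @param standardize Standardize each session's ratings to mean 0, sd 1
#'   before fitting (default `TRUE`, the raw-slider-data path).  Set to
#'   `FALSE` when ratings are already on the model's z-scale, as emitted by
#'   [simulate_session()].
#' @param min_rated Minimum usable ratings per subject (default 5).
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `sborg_hfit`: list with `draws` (a
#'   [coda::mcmc.list]), `subjects`, `diagnostics` (split R-hat and effective
#'   sample size per monitored parameter; divergent-transition count is `NA`,
#'   undefined for this sampler family), `excluded`, `settings`, `seed`.
#' @export
fit_happiness_hier <- function(sessions, priors = prior_config(),
                               chains = 4L, adapt = 500L, warmup = 1000L,
                               iter = 1000L, seed = 1L, standardize = TRUE,
                               min_rated = 5L, quiet = TRUE) {
  stopifnot(is.list(sessions), length(sessions) >= 1L,
            inherits(priors, "sborg_prior_config"))
  prep <- prepare_cell(sessions, standardize = standardize,
                       min_rated = min_rated)
  if (length(prep$subjects) < 2L)
    stop("need at least 2 usable subjects in a condition cell", call. = FALSE)
  dat <- c(prep$data,
           list(prior_mean_loc = priors$mean_loc,
                prior_mean_scale = priors$mean_scale,
                prior_sd_scale = priors$sd_scale,
                prior_noise_scale = priors$noise_scale))
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch))
  jm <- rjags::jags.model(textConnection(happiness_model_string), data = dat,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = quiet)
  if (warmup > 0)
    stats::update(jm, warmup, progress.bar = if (quiet) "none" else "text")
  monitors <- c("mu_w", "mu_g", "gamma_group", "sigma_w", "sigma_g",
                "w", "gam", "sigma_eps")
  draws <- rjags::coda.samples(jm, monitors, n.iter = iter,
                               progress.bar = if (quiet) "none" else "text")
  diag <- fit_diagnostics(draws)
  gpars <- c("mu_w[1]", "mu_w[2]", "mu_w[3]", "mu_w[4]", "gamma_group")
  bad <- diag$parameter[diag$parameter %in% gpars & diag$rhat > 1.05]
  if (length(bad))
    warning("split R-hat > 1.05 for: ", paste(bad, collapse = ", "),
            "; treat this fit as non-converged", call. = FALSE)
  structure(list(draws = draws, subjects = prep$subjects,
                 diagnostics = diag, excluded = prep$excluded,
                 settings = list(chains = chains, adapt = adapt,
                                 warmup = warmup, iter = iter,
                                 standardize = standardize,
                                 sampler = "jags", divergences = NA_integer_),
                 seed = as.integer(seed)),
            class = "sborg_hfit")
}

# Assemble concatenated regressor vectors and rated-trial observations for
# one condition cell.  Returns JAGS data, kept subject ids, exclusions.
prepare_cell <- function(sessions, standardize = TRUE, min_rated = 5L) {
  CR <- EV <- RPE <- numeric(0)
  robs <- numeric(0); rtrial <- integer(0); rsubj <- integer(0)
  first <- last <- integer(0)
  subjects <- character(0); excluded <- character(0)
  off <- 0L
  for (ses in sessions) {
    sid <- as.character(ses$subject_id[1L])
    reg <- build_regressors(ses)
    ratings <- reg$rating[reg$rated]
    if (length(ratings) < min_rated) {
      warning("excluding ", sid, ": only ", length(ratings),
              " usable ratings", call. = FALSE)
      excluded <- c(excluded, sid)
      next
    }
    if (standardize) {
      z <- tryCatch(zscore_ratings(ratings), error = function(e) NULL)
      if (is.null(z)) {
        warning("excluding ", sid, ": degenerate (constant) ratings",
                call. = FALSE)
        excluded <- c(excluded, sid)
        next
      }
      ratings <- z
    }
    s_idx <- length(subjects) + 1L
    subjects <- c(subjects, sid)
    first <- c(first, off + 1L)
    last <- c(last, off + nrow(reg))
    CR <- c(CR, reg$CR); EV <- c(EV, reg$EV); RPE <- c(RPE, reg$RPE)
    rtrial <- c(rtrial, off + which(reg$rated))
    rsubj <- c(rsubj, rep(s_idx, length(ratings)))
    robs <- c(robs, ratings)
    off <- off + nrow(reg)
  }
  list(data = list(S = length(subjects), first = first, last = last,
                   CR = CR, EV = EV, RPE = RPE,
                   Nobs = length(robs), robs = robs,
                   rtrial = rtrial, rsubj = rsubj),
       subjects = subjects, excluded = excluded)
}

# Split R-hat and effective sample size for every monitored parameter.
fit_diagnostics <- function(draws) {
  mat_list <- lapply(draws, as.matrix)
  params <- colnames(mat_list[[1L]])
  rhat <- vapply(params, function(p)
    split_rhat(lapply(mat_list, function(m) m[, p])), numeric(1))
  ess <- as.numeric(coda::effectiveSize(draws)[params])
  data.frame(parameter = params, rhat = rhat, ess = ess,
             row.names = NULL)
}

# Split R-hat: each chain halved, potential scale reduction over the halves.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[(n + 1L):(2L * n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Group-level posterior draws of a fit
#'
#' @param fit An `sborg_hfit`.
#' @return Matrix (all chains stacked) with columns `w0..w3` (group means)
#'   and `gamma` (group forgetting factor on the natural scale).
#' @export
group_draws <- function(fit) {
  stopifnot(inherits(fit, "sborg_hfit"))
  m <- as.matrix(do.call(rbind, lapply(fit$draws, as.matrix)))
  out <- m[, c("mu_w[1]", "mu_w[2]", "mu_w[3]", "mu_w[4]", "gamma_group")]
  colnames(out) <- c("w0", "w1", "w2", "w3", "gamma")
  out
}

#' Per-subject posterior means of individual-level parameters
#'
#' @param fit An `sborg_hfit`.
#' @return Data frame: `subject_id`, `w0..w3`, `gamma`, `rating_noise_sd`.
#' @export
individual_means <- function(fit) {
  stopifnot(inherits(fit, "sborg_hfit"))
  m <- colMeans(do.call(rbind, lapply(fit$draws, as.matrix)))
  S <- length(fit$subjects)
  data.frame(
    subject_id = fit$subjects,
    w0 = m[sprintf("w[%d,1]", seq_len(S))],
    w1 = m[sprintf("w[%d,2]", seq_len(S))],
    w2 = m[sprintf("w[%d,3]", seq_len(S))],
    w3 = m[sprintf("w[%d,4]", seq_len(S))],
    gamma = m[sprintf("gam[%d]", seq_len(S))],
    rating_noise_sd = m[sprintf("sigma_eps[%d]", seq_len(S))],
    row.names = NULL)
}

#' Posterior summary table
#'
#' Mean, standard deviation, and 95% highest density interval per parameter.
#'
#' @param draws An `sborg_hfit` (summarizes the group-level parameters), or a
#'   numeric matrix / named list of draw vectors.
#' @param mass HDI mass (default 0.95).
#' @return Data frame: `parameter`, `mean`, `sd`, `hdi_low`, `hdi_high`.
#' @export
posterior_summary <- function(draws, mass = 0.95) {
  if (inherits(draws, "sborg_hfit")) draws <- group_draws(draws)
  if (is.matrix(draws))
    draws <- stats::setNames(lapply(seq_len(ncol(draws)),
                                    function(j) draws[, j]),
                             colnames(draws))
  stopifnot(is.list(draws), length(draws) >= 1L)
  rows <- lapply(names(draws), function(p) {
    x <- draws[[p]]
    h <- if (stats::var(x) == 0) c(x[1L], x[1L]) else hdi(x, mass)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               hdi_low = h[1L], hdi_high = h[2L])
  })
  do.call(rbind, rows)
}

#' Predicted ratings from a fitted cell
#'
#' Forward happiness predictions at every rated trial of the given sessions,
#' using each subject's individual-level posterior means.
#'
#' @param fit An `sborg_hfit`.
#' @param sessions Sessions of subjects covered by the fit.
#' @param standardize Compare against standardized ratings (must match how
#'   the fit was run); default taken from the fit.
#' @return Data frame: `subject_id`, `med_state`, `trial_index`, `actual`,
#'   `predicted`.
#' @export
predict_from_fit <- function(fit, sessions,
                             standardize = fit$settings$standardize) {
  stopifnot(inherits(fit, "sborg_hfit"))
  ind <- individual_means(fit)
  rows <- lapply(sessions, function(ses) {
    sid <- as.character(ses$subject_id[1L])
    if (sid %in% fit$excluded) return(NULL)
    if (!sid %in% ind$subject_id)
      stop("subject ", sid, " not covered by the fit", call. = FALSE)
    p <- ind[ind$subject_id == sid, ]
    hp <- happiness_params(p$w0, p$w1, p$w2, p$w3, p$gamma,
                           max(p$rating_noise_sd, 0.01))
    reg <- build_regressors(ses)
    pred <- predict_happiness(hp, reg)[reg$rated]
    actual <- reg$rating[reg$rated]
    if (standardize) actual <- zscore_ratings(actual)
    data.frame(subject_id = sid, med_state = ses$med_state[1L],
               trial_index = reg$trial_index[reg$rated],
               actual = actual, predicted = pred)
  })
  do.call(rbind, rows)
}

#' Tidy draw table of a fit
#'
#' @param fit An `sborg_hfit`.
#' @return Data frame `chain`, `draw`, `parameter`, `value`, one row per
#'   retained draw per monitored parameter.
#' @export
tidy_draws <- function(fit) {
  stopifnot(inherits(fit, "sborg_hfit"))
  rows <- lapply(seq_along(fit$draws), function(ch) {
    m <- as.matrix(fit$draws[[ch]])
    data.frame(chain = ch, draw = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  })
  do.call(rbind, rows)
}

#' @export
print.sborg_hfit <- function(x, ...) {
  cat("Hierarchical happiness-model fit:", length(x$subjects), "subjects,",
      x$settings$chains, "chains x", x$settings$iter, "retained draws\n")
  gp <- c("mu_w[1]", "mu_w[2]", "mu_w[3]", "mu_w[4]", "gamma_group")
  d <- x$diagnostics[x$diagnostics$parameter %in% gp, ]
  cat("max split R-hat (group params):", round(max(d$rhat), 3),
      " min ESS:", round(min(d$ess)), "\n")
  print(posterior_summary(x), digits = 4)
  invisible(x)
}
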