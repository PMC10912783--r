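# Independent oracles: deliberately naive reimplementations used only to
# check the package's vectorized/library-backed code paths.

# Decayed sum by explicit double loop over (t, j).
oracle_decayed_sum <- function(x, gamma, t) {
  s <- 0
  for (j in seq_len(t)) s <- s + gamma^(t - j) * x[j]
  s
}

# Happiness prediction evaluated term by term from the decayed-sum oracle.
oracle_happiness <- function(w0, w1, w2, w3, gamma, CR, EV, RPE, t) {
  w0 + w1 * oracle_decayed_sum(CR, gamma, t) +
    w2 * oracle_decayed_sum(EV, gamma, t) +
    w3 * oracle_decayed_sum(RPE, gamma, t)
}

# Narrowest-interval HDI by exhaustive search over every contiguous window.
oracle_hdi <- function(samples, mass) {
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  best <- c(x[1], x[1 + m]); best_w <- x[1 + m] - x[1]
  for (i in seq_len(n - m)) {
    w <- x[i + m] - x[i]
    if (w < best_w) { best_w <- w; best <- c(x[i], x[i + m]) }
  }
  best
}

# Textbook one-sample t statistic, p-value, and CI.
oracle_t_test <- function(x, conf = 0.95) {
  n <- length(x)
  se <- sd(x) / sqrt(n)
  t <- mean(x) / se
  list(t = t, p = 2 * pt(-abs(t), n - 1),
       ci = mean(x) + c(-1, 1) * qt(1 - (1 - conf) / 2, n - 1) * se)
}

# Exact two-sided rank-sum p-value by enumerating every group assignment
# (tie-free data only; mirrors the exact Mann-Whitney construction).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2   # Mann-Whitney U of group a
  combs <- combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p_le <- mean(us <= obs)
  p_ge <- mean(us >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# Per-subject maximum-likelihood fit of the happiness model by direct
# optimization (gamma on the logit scale, noise on the log scale).
oracle_ml_happiness <- function(reg, ratings, rated_idx) {
  nll <- function(par) {
    g <- plogis(par[5]); sig <- exp(par[6])
    pred <- par[1] +
      par[2] * vapply(rated_idx, function(t) oracle_decayed_sum(reg$CR, g, t),
                      numeric(1)) +
      par[3] * vapply(rated_idx, function(t) oracle_decayed_sum(reg$EV, g, t),
                      numeric(1)) +
      par[4] * vapply(rated_idx, function(t) oracle_decayed_sum(reg$RPE, g, t),
                      numeric(1))
    -sum(dnorm(ratings, pred, sig, log = TRUE))
  }
  fit <- optim(c(0, 0, 0, 0, 0, 0), nll, method = "BFGS",
               control = list(maxit = 500))
  c(w0 = fit$par[1], w1 = fit$par[2], w2 = fit$par[3], w3 = fit$par[4],
    gamma = plogis(fit$par[5]), sigma = exp(fit$par[6]))
}
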