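# Posterior comparison of condition cells: highest density intervals,
# difference distributions, posterior Cohen's d, credible fractions.

#' Highest density interval of a sample
#'
#' Narrowest contiguous interval of the sorted draws containing
#' `ceiling(mass * n)` of them.  For multimodal samples this still returns a
#' single interval (documented limitation); ties between equally narrow
#' windows resolve to the left-most.
#'
#' @param samples Numeric draws (at least 2).
#' @param mass Probability mass in `(0, 1]` (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 2L) stop("need at least 2 draws", call. = FALSE)
  if (mass <= 0 || mass > 1) stop("`mass` must be in (0, 1]", call. = FALSE)
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[(m + 1L):n] - x[1L:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Difference distribution of two draw vectors
#'
#' Element-wise `A - B` after aligning lengths: the longer vector is thinned
#' to evenly spaced draws matching the shorter.  Cells are fitted
#' independently, so any pairing is valid; index pairing keeps the result
#' reproducible.  Sign convention in reports: ICD minus non-ICD, On minus
#' Off.
#'
#' @param draws_a,draws_b Numeric posterior draws.
#' @return Numeric difference draws.
#' @export
difference_distribution <- function(draws_a, draws_b) {
  if (length(draws_a) == 0L || length(draws_b) == 0L)
    stop("empty draw vector", call. = FALSE)
  n <- min(length(draws_a), length(draws_b))
  thin <- function(x) if (length(x) == n) x else
    x[round(seq(1L, length(x), length.out = n))]
  thin(draws_a) - thin(draws_b)
}

#' Posterior Cohen's d between two draw distributions
#'
#' Difference of posterior means scaled by the root mean of the two
#' posterior variances: `(mean(A) - mean(B)) / sqrt((var(A) + var(B)) / 2)`.
#'
#' @param draws_a,draws_b Numeric posterior draws.
#' @return Cohen's d; `NA` with a warning when both variances are zero.
#' @export
cohens_d_posterior <- function(draws_a, draws_b) {
  if (length(draws_a) == 0L || length(draws_b) == 0L)
    stop("empty draw vector", call. = FALSE)
  pooled <- sqrt((stats::var(draws_a) + stats::var(draws_b)) / 2)
  num <- mean(draws_a) - mean(draws_b)
  if (pooled == 0) {
    if (num == 0) return(0)
    warning("both posterior variances are zero; Cohen's d undefined")
    return(NA_real_)
  }
  num / pooled
}

#' Cohen's d reconstructed from posterior summaries
#'
#' Recovers the posterior Cohen's d from printed posterior means and 95%
#' highest density intervals under a normal approximation: each posterior's
#' standard deviation is taken as the interval width divided by 3.92 (twice
#' the 97.5% normal quantile).
#'
#' @param mean_a,mean_b Posterior means.
#' @param hdi_a,hdi_b Length-2 vectors, the 95% HDIs.
#' @return Cohen's d.
#' @export
cohens_d_from_summary <- function(mean_a, hdi_a, mean_b, hdi_b) {
  stopifnot(length(hdi_a) == 2L, length(hdi_b) == 2L)
  sd_a <- (hdi_a[2L] - hdi_a[1L]) / 3.92
  sd_b <- (hdi_b[2L] - hdi_b[1L]) / 3.92
  (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Credible-difference fractions
#'
#' Empirical fractions of difference draws below and above zero; exact zeros
#' are split evenly between the two sides so the fractions always sum to 1.
#'
#' @param diff_draws Numeric difference draws.
#' @return Named numeric `c(below = ..., above = ...)`.
#' @export
credible_fraction <- function(diff_draws) {
  if (length(diff_draws) == 0L) stop("empty draw vector", call. = FALSE)
  zero <- mean(diff_draws == 0)
  c(below = mean(diff_draws < 0) + zero / 2,
    above = mean(diff_draws > 0) + zero / 2)
}

# Extract a named list of group-level draw vectors from a fit or list.
group_draw_list <- function(x) {
  if (inherits(x, "sborg_hfit")) {
    m <- group_draws(x)
    stats::setNames(lapply(seq_len(ncol(m)), function(j) m[, j]),
                    colnames(m))
  } else if (is.list(x) && all(vapply(x, is.numeric, logical(1)))) {
    x
  } else stop("expected an `sborg_hfit` or a named list of draw vectors",
              call. = FALSE)
}

#' Compare two condition cells' group-level posteriors
#'
#' Per-parameter report for a pair of cells: posterior means and 95% HDIs of
#' each cell, the A - B difference distribution's mean and 95% HDI, posterior
#' Cohen's d, and credible-difference fractions.  Differences exceeding the
#' 97.5% credible cutoff on either side are flagged.
#'
#' @param cell_a,cell_b `sborg_hfit` objects (see [fit_happiness_hier()]) or
#'   named lists of group-level draw vectors.  Parameter sets must match.
#' @param mass HDI mass (default 0.95).
#' @param credible_cutoff One-sided credible-fraction threshold
#'   (default 0.975).
#' @return A data frame of class `sborg_comparison` with one row per
#'   parameter.
#' @export
compare_cells <- function(cell_a, cell_b, mass = 0.95,
                          credible_cutoff = 0.975) {
  a <- group_draw_list(cell_a)
  b <- group_draw_list(cell_b)
  if (!setequal(names(a), names(b)))
    stop("parameter sets differ between cells", call. = FALSE)
  pars <- names(a)
  rows <- lapply(pars, function(p) {
    ha <- hdi(a[[p]], mass); hb <- hdi(b[[p]], mass)
    dd <- difference_distribution(a[[p]], b[[p]])
    hd <- hdi(dd, mass)
    fr <- credible_fraction(dd)
    data.frame(parameter = p,
               mean_a = mean(a[[p]]), hdi_a_low = ha[1], hdi_a_high = ha[2],
               mean_b = mean(b[[p]]), hdi_b_low = hb[1], hdi_b_high = hb[2],
               diff_mean = mean(dd), diff_hdi_low = hd[1],
               diff_hdi_high = hd[2],
               cohens_d = cohens_d_posterior(a[[p]], b[[p]]),
               frac_below = fr[["below"]], frac_above = fr[["above"]],
               credible = max(fr) > credible_cutoff)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sborg_comparison", "data.frame")
  out
}

#' @export
print.sborg_comparison <- function(x, digits = 4, ...) {
  cat("Group-level posterior comparison (A - B)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
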