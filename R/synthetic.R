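#' Planted-burst Poisson count series
#'
#' Generates a Poisson count series with piecewise-constant rate: a
#' quiescent background punctuated by bursts over given intervals.  This
#' emulates pooled multielectrode activity and provides ground truth for
#' validating the event detector.
#'
#' @param duration total duration (ms)
#' @param dt_bin bin width (ms)
#' @param background_rate background count rate (counts/ms)
#' @param burst_rate count rate inside bursts (counts/ms)
#' @param burst_intervals two-column matrix of disjoint `(start, end)` times
#'   in ms (half-open)
#' @param seed optional RNG seed
#' @return list with `series` (a [count_series()]) and `truth` (data frame
#'   of planted onsets/offsets in bins)
#' @export
make_planted_count_series <- function(duration, dt_bin = 1,
                                      background_rate = 0.05,
                                      burst_rate = 5,
                                      burst_intervals = NULL,
                                      seed = NULL) {
  stopifnot(background_rate >= 0, burst_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration / dt_bin))
  lam <- rep(background_rate * dt_bin, n)
  truth <- data.frame(onset_bin = integer(0), offset_bin = integer(0))
  if (!is.null(burst_intervals)) {
    bi <- matrix(burst_intervals, ncol = 2)
    if (nrow(bi) > 1) {
      o <- order(bi[, 1])
      bi <- bi[o, , drop = FALSE]
      if (any(bi[-1, 1] < bi[-nrow(bi), 2]))
        stop("make_planted_count_series: burst intervals must be disjoint")
    }
    for (i in seq_len(nrow(bi))) {
      a <- as.integer(floor(bi[i, 1] / dt_bin))
      b <- min(as.integer(ceiling(bi[i, 2] / dt_bin)), n)
      if (b > a) {
        lam[(a + 1):b] <- burst_rate * dt_bin
        truth <- rbind(truth, data.frame(onset_bin = a, offset_bin = b))
      }
    }
  }
  list(series = count_series(rpois(n, lam), dt_bin), truth = truth)
}

#' Sample event sizes from the exponential-plus-Gaussian mixture
#'
#' Draws i.i.d. sizes from the two-component law fitted by
#' [fit_size_mixture()]: with probability `p0` a shifted exponential
#' `x0 + Exp(tau0)`, otherwise a Gaussian `N(m1, sigma1)` truncated below
#' `x0`.
#'
#' @param n sample size
#' @param p0 exponential weight in `[0, 1]`
#' @param tau0 exponential scale
#' @param x0 shift / truncation point
#' @param m1,sigma1 Gaussian location and scale
#' @param seed optional RNG seed
#' @return numeric vector of sizes
#' @export
make_mixture_sample <- function(n, p0, tau0, x0, m1, sigma1, seed = NULL) {
  stopifnot(p0 >= 0, p0 <= 1, tau0 > 0, sigma1 > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  from_exp <- runif(n) < p0
  x <- numeric(n)
  x[from_exp] <- x0 + rexp(sum(from_exp), 1 / tau0)
  k <- sum(!from_exp)
  if (k) {
    # inverse-CDF sampling of the truncated Gaussian
    lo <- pnorm((x0 - m1) / sigma1)
    u <- runif(k, lo, 1)
    x[!from_exp] <- m1 + sigma1 * qnorm(u)
  }
  x
}

#' Analytic CDF of the size mixture (for goodness-of-fit checks)
#'
#' @param q quantiles
#' @param p0,tau0,x0,m1,sigma1 mixture parameters as in
#'   [make_mixture_sample()]
#' @return cumulative probability at `q`
#' @export
mixture_cdf <- function(q, p0, tau0, x0, m1, sigma1) {
  Fe <- ifelse(q < x0, 0, 1 - exp(-(q - x0) / tau0))
  z0 <- pnorm((x0 - m1) / sigma1)
  Fg <- ifelse(q < x0, 0, (pnorm((q - m1) / sigma1) - z0) / (1 - z0))
  p0 * Fe + (1 - p0) * Fg
}

#' Named working points in the excitation-inhibition plane
#'
#' Reference `(w_exc, w_inh)` points used in the analyses: the reference
#' point `(1, 1)` on the brink of the oscillatory instability, three
#' subcritical points with mixed network-spike / quasi-orbit statistics,
#' three points of increasing excitation at fixed inhibition used for the
#' avalanche distributions, and a supercritical point.
#'
#' @return data frame with `name`, `w_exc`, `w_inh`
#' @export
preset_grid <- function() {
  data.frame(
    name = c("reference", "fig5D", "fig5E", "fig5F",
             "fig6A", "fig6B", "fig6C", "s3_supercritical"),
    w_exc = c(1.0, 0.82, 0.82, 0.88, 0.90, 0.94, 1.00, 1.2),
    w_inh = c(1.0, 0.70, 0.55, 0.55, 1.00, 1.00, 1.00, 0.4))
}
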