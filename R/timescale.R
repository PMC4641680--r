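#' Low-pass integrate a rate series (generic fatigue variable)
#'
#' Integrates \eqn{\dot f = -f/\tau^* + \nu(t)} over bins of width `dt`
#' with the exact per-bin exponential update
#' \eqn{f_{k+1} = f_k e^{-\Delta/\tau^*} + \nu_k \tau^*(1 - e^{-\Delta/\tau^*})},
#' assuming the rate is constant within a bin.  The value stored for bin
#' `k` is the state at the *start* of the bin, so `f[k]` reflects only
#' activity strictly before bin `k`.  Under constant rate the steady state
#' is \eqn{\nu \tau^*}.
#'
#' @param rate rate per bin; any unit (typically Hz)
#' @param dt bin width, in the same time unit as `tau_star`
#' @param tau_star integrator time constant
#' @param f0 initial value
#' @return numeric vector of `f` at the start of each bin
#' @export
integrate_fatigue <- function(rate, dt, tau_star, f0 = 0) {
  stopifnot(tau_star > 0, dt > 0)
  a <- exp(-dt / tau_star)
  drive <- rate * tau_star * (1 - a)
  n <- length(rate)
  if (!n) return(numeric(0))
  # f[k+1] = a f[k] + drive[k]: linear recursion via stats::filter
  f <- stats::filter(c(f0, drive[-n]), a, method = "recursive",
                     init = 0)
  as.numeric(f)
}

#' Effective linear-integrator timescale of short-term depression
#'
#' Linearising the resource dynamics around its stationary value
#' \eqn{\langle r\rangle = 1/(1 + u_{STD}\langle\nu\rangle\tau_{STD})}
#' shows that the resources behave as a simple linear integrator with
#' time constant
#' \deqn{\tau^*_{opt} = \frac{\tau_{STD}}{1 + u_{STD}\langle\nu\rangle\tau_{STD}}
#'      = \tau_{STD}\,\langle r\rangle.}
#'
#' @param tau_STD recovery time (s)
#' @param u_STD utilisation fraction in (0,1)
#' @param mean_rate mean firing rate (Hz)
#' @return effective timescale (s)
#' @export
effective_timescale <- function(tau_STD, u_STD, mean_rate) {
  stopifnot(tau_STD > 0, u_STD > 0, u_STD < 1, mean_rate >= 0)
  tau_STD / (1 + u_STD * mean_rate * tau_STD)
}

#' Correlation scan over candidate fatigue timescales
#'
#' For each candidate timescale the rate series is low-pass integrated
#' ([integrate_fatigue()]); the integrator value at the bin immediately
#' preceding each event onset is Pearson-correlated with the event size.
#' A fatigue mechanism with timescale \eqn{\tau} shows up as a negative
#' peak of the correlation near \eqn{\tau}.  Significance is calibrated by
#' permuting the onset values `B` times (the same permutation across the
#' whole grid, preserving the curve's cross-timescale correlation): the
#' reported per-timescale bound is the 5th percentile of the permuted
#' correlations (one-sided, matching "95% of surrogate correlations fall
#' above"), while optima are additionally gated on the 5th percentile of
#' the *minimum* of the null curves, which controls the family-wise error
#' of scanning many timescales.  Optima are the local minima of the curve
#' below both bounds, merged when closer than a factor 2 in timescale
#' (keeping the deepest), each refined off-grid by a local parabola in
#' log-timescale.
#'
#' @param rate rate per bin (Hz)
#' @param dt_bin bin width (s)
#' @param events an `event_list` (network spikes and quasi-orbits are both
#'   used); onsets are read from `onset_bin`
#' @param tau_grid candidate timescales (s), log-spaced by default
#' @param B number of permutations for the surrogate bound
#' @param method correlation method (`"pearson"` default, `"spearman"`
#'   available)
#' @param seed optional RNG seed for the permutations
#' @return object of class `correlation_scan`: list with `tau_star`,
#'   `correlation`, `surrogate_bound` (pointwise), `familywise_bound`,
#'   and `optima` (data frame `tau_star_opt`, `tau_star_grid`,
#'   `correlation`)
#' @export
correlation_scan <- function(rate, dt_bin, events,
                             tau_grid = 10^seq(log10(0.05), log10(100),
                                               length.out = 50),
                             B = 1000, method = c("pearson", "spearman"),
                             seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(diff(tau_grid) > 0))
  onsets <- events$onset_bin
  sizes <- events$size
  keep <- onsets >= 1  # need at least one bin strictly before the onset
  onsets <- onsets[keep]; sizes <- sizes[keep]
  n <- length(onsets)
  if (n < 30) stop("correlation_scan: need at least 30 events")
  if (!is.null(seed)) set.seed(seed)
  perms <- lapply(seq_len(B), function(b) sample.int(n))
  K <- length(tau_grid)
  # f[j] is the state at the start of bin j; the value "just before" an
  # event starting at 0-based bin b is the state at the start of that bin,
  # i.e. f[b + 1] in 1-based indexing, which excludes the event itself
  FO <- vapply(tau_grid, function(tau)
    integrate_fatigue(rate, dt_bin, tau)[onsets + 1L], numeric(n))
  if (method == "spearman") {
    FO <- apply(FO, 2, rank)
    sizes_r <- rank(sizes)
  } else sizes_r <- sizes
  corr <- suppressWarnings(as.numeric(cor(FO, sizes_r)))
  # null curves: one permutation of the onset values applied across the
  # whole grid, preserving the cross-timescale correlation structure
  Z <- scale(FO)
  zs <- as.numeric(scale(sizes_r))
  null_curves <- vapply(perms, function(pm)
    as.numeric(crossprod(Z[pm, , drop = FALSE], zs)) / (n - 1), numeric(K))
  # pointwise one-sided 5% bound (the reference line of the scan plot)
  bound <- apply(null_curves, 1, quantile, probs = 0.05, names = FALSE,
                 na.rm = TRUE)
  # family-wise gate for calling optima: distribution of the null curve's
  # minimum over the grid (a pointwise bound cannot calibrate an argmin)
  fw_bound <- quantile(apply(null_curves, 2, min, na.rm = TRUE), 0.05,
                       names = FALSE, na.rm = TRUE)
  loc_min <- which(diff(sign(diff(corr))) > 0) + 1L
  if (length(corr) >= 2) {
    if (corr[1] < corr[2]) loc_min <- c(1L, loc_min)
    if (corr[K] < corr[K - 1]) loc_min <- c(loc_min, K)
  }
  loc_min <- loc_min[corr[loc_min] < pmin(bound[loc_min], fw_bound)]
  # merge minima closer than a factor 2, keeping the deepest
  if (length(loc_min) > 1) {
    loc_min <- loc_min[order(tau_grid[loc_min])]
    merged <- loc_min[1]
    for (i in loc_min[-1]) {
      last <- merged[length(merged)]
      if (tau_grid[i] / tau_grid[last] < 2) {
        if (corr[i] < corr[last]) merged[length(merged)] <- i
      } else merged <- c(merged, i)
    }
    loc_min <- merged
  }
  # sub-grid refinement: parabola through the three points around each
  # minimum in (log tau, correlation) removes the grid quantisation
  refine <- function(i) {
    if (i <= 1 || i >= K) return(tau_grid[i])
    lt <- log(tau_grid[(i - 1):(i + 1)])
    y <- corr[(i - 1):(i + 1)]
    denom <- (y[1] - 2 * y[2] + y[3])
    if (denom <= 0) return(tau_grid[i])
    delta <- 0.5 * (y[1] - y[3]) / denom
    exp(lt[2] + delta * (lt[3] - lt[2]))
  }
  structure(list(tau_star = tau_grid, correlation = corr,
                 surrogate_bound = bound, familywise_bound = fw_bound,
                 optima = data.frame(
                   tau_star_opt = vapply(loc_min, refine, numeric(1)),
                   tau_star_grid = tau_grid[loc_min],
                   correlation = corr[loc_min])),
            class = "correlation_scan")
}

#' @export
print.correlation_scan <- function(x, ...) {
  cat(sprintf("correlation_scan: %d timescales in [%.3g, %.3g] s\n",
              length(x$tau_star), min(x$tau_star), max(x$tau_star)))
  if (nrow(x$optima))
    for (i in seq_len(nrow(x$optima)))
      cat(sprintf("  optimum: tau* = %.3g s (r = %.3f)\n",
                  x$optima$tau_star_opt[i], x$optima$correlation[i]))
  else cat("  no significant negative peak\n")
  invisible(x)
}

#' Recover depression parameters from effective-timescale measurements
#'
#' Nonlinear least squares of the effective-timescale relation
#' \eqn{\tau^*_{opt} = \tau_{STD}/(1 + u_{STD}\langle\nu\rangle\tau_{STD})}
#' over pairs of mean rate and scan-optimal timescale collected at several
#' working points, with bounds \eqn{\tau_{STD} \in (0, 10]} s,
#' \eqn{u_{STD} \in (0, 1)}.
#'
#' @param mean_rate mean firing rates (Hz), one per working point
#' @param tau_opt scan-optimal timescales (s)
#' @param start optional start values `c(tau_STD, u_STD)`
#' @return object of class `std_recovery`: list with `tau_STD_hat`,
#'   `u_STD_hat` (and standard errors `tau_STD_se`, `u_STD_se`),
#'   `residual`, and the underlying `nls` fit
#' @export
fit_std_params <- function(mean_rate, tau_opt, start = NULL) {
  stopifnot(length(mean_rate) == length(tau_opt))
  ok <- is.finite(mean_rate) & is.finite(tau_opt)
  mean_rate <- mean_rate[ok]; tau_opt <- tau_opt[ok]
  if (length(mean_rate) < 4)
    stop("fit_std_params: need at least 4 (rate, tau) pairs")
  if (max(mean_rate) / min(mean_rate) < 2)
    warning("fit_std_params: mean rates span less than a factor 2; ",
            "the two parameters are weakly identifiable")
  if (is.null(start)) start <- c(tau_STD = max(tau_opt), u_STD = 0.3)
  df <- data.frame(nu = mean_rate, tau = tau_opt)
  fit <- minpack.lm::nlsLM(tau ~ tau_STD / (1 + u_STD * nu * tau_STD),
                           data = df, start = as.list(start),
                           lower = c(1e-4, 1e-4), upper = c(10, 1 - 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  structure(list(tau_STD_hat = unname(est["tau_STD"]),
                 u_STD_hat = unname(est["u_STD"]),
                 tau_STD_se = unname(se[1]), u_STD_se = unname(se[2]),
                 residual = sqrt(mean(stats::resid(fit)^2)), fit = fit,
                 pairs = df),
            class = "std_recovery")
}

#' @export
print.std_recovery <- function(x, ...) {
  cat(sprintf("std_recovery: tau_STD = %.3f +/- %.3f s, u_STD = %.3f +/- %.3f\n",
              x$tau_STD_hat, x$tau_STD_se, x$u_STD_hat, x$u_STD_se))
  invisible(x)
}

#' Correlation between a pre-event precursor and event size
#'
#' Pearson correlation between the value of a precursor signal (e.g. the
#' available synaptic resources) at the bin immediately preceding each
#' event onset and the event size, with a permutation p-value (two-sided
#' unless `alternative` is given).
#'
#' @param events an `event_list`
#' @param precursor vector with one value per series bin (e.g. `r_E`
#'   sampled at the bin grid)
#' @param B number of permutations
#' @param alternative `"two.sided"`, `"less"` (negative correlation) or
#'   `"greater"`
#' @param seed optional RNG seed
#' @return list with `correlation`, `p_value`, `n`
#' @export
precursor_correlation <- function(events, precursor, B = 1000,
                                  alternative = c("two.sided", "less",
                                                  "greater"),
                                  seed = NULL) {
  alternative <- match.arg(alternative)
  onsets <- events$onset_bin
  keep <- onsets >= 1 & onsets < length(precursor)
  onsets <- onsets[keep]
  sizes <- events$size[keep]
  n <- length(onsets)
  if (n < 5) stop("precursor_correlation: too few events")
  pv <- precursor[onsets]  # value in the last bin strictly before onset
  r <- cor(pv, sizes)
  if (!is.null(seed)) set.seed(seed)
  rp <- replicate(B, cor(pv[sample.int(n)], sizes))
  p <- switch(alternative,
              two.sided = mean(abs(rp) >= abs(r)),
              less = mean(rp <= r),
              greater = mean(rp >= r))
  list(correlation = r, p_value = p, n = n)
}
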