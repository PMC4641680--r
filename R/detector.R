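#' Spike-count series
#'
#' Nonnegative integer spike counts per fixed time bin: the common currency
#' of the event detector and the event statistics, for both simulated and
#' recorded (pooled multielectrode) activity.
#'
#' @param counts nonnegative integer vector
#' @param dt_bin bin width (ms); the detector is validated for widths
#'   between 0.25 and 8 ms
#' @param t0 time of the left edge of the first bin (ms)
#' @return an object of class `count_series`
#' @export
count_series <- function(counts, dt_bin, t0 = 0) {
  counts <- as.integer(counts)
  if (length(counts) && (anyNA(counts) || any(counts < 0)))
    stop("count_series: counts must be nonnegative integers")
  stopifnot(dt_bin > 0)
  structure(list(counts = counts, dt_bin = dt_bin, t0 = t0),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("count_series: %d bins of %g ms (%.1f s), %d spikes\n",
              length(x$counts), x$dt_bin,
              length(x$counts) * x$dt_bin / 1000, sum(x$counts)))
  invisible(x)
}

#' Bin pooled spike times into a count series
#'
#' Pools spike timestamps from all channels into one series with
#' `count[k] =` number of spikes in the half-open bin
#' `[t0 + k dt_bin, t0 + (k+1) dt_bin)` (0-based `k`).
#'
#' @param times spike times (ms), any order; a data frame with a `time_ms`
#'   column (e.g. from [read_spike_table()]) is also accepted
#' @param dt_bin bin width (ms)
#' @param t0 origin (ms)
#' @param t_end optional end of the observation window (ms); defaults to
#'   just past the last spike
#' @return a [count_series()] object
#' @export
bin_spikes <- function(times, dt_bin, t0 = 0, t_end = NULL) {
  if (is.data.frame(times)) times <- times$time_ms
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    stop("bin_spikes: spike times must be finite")
  if (!length(times)) return(count_series(integer(0), dt_bin, t0))
  if (is.null(t_end)) t_end <- max(times) + dt_bin / 2
  n_bins <- max(1L, as.integer(ceiling((t_end - t0) / dt_bin)))
  idx <- floor((times - t0) / dt_bin)
  idx <- idx[idx >= 0 & idx < n_bins]
  counts <- tabulate(idx + 1L, nbins = n_bins)
  count_series(counts, dt_bin, t0)
}

#' Rebin a count series by an integer factor
#'
#' @param series a [count_series()]
#' @param k integer aggregation factor; trailing bins that do not fill a
#'   complete group are dropped
#' @return a [count_series()] with bin width `k * dt_bin`
#' @export
rebin_counts <- function(series, k) {
  stopifnot(inherits(series, "count_series"), k >= 1, k == round(k))
  k <- as.integer(k)
  n <- (length(series$counts) %/% k) * k
  if (n == 0) return(count_series(integer(0), series$dt_bin * k, series$t0))
  m <- matrix(series$counts[seq_len(n)], nrow = k)
  count_series(as.integer(colSums(m)), series$dt_bin * k, series$t0)
}

#' Detector configuration
#'
#' @param mode `"ns_quasiorbit"` for network spikes / quasi-orbits (free
#'   two-state HMM plus a surrogate-calibrated minimum duration) or
#'   `"avalanche"` (low state clamped to near-silence, no thresholds)
#' @param dt_bin bin width (ms) the series should be analysed at
#' @param P_surrogate tail probability defining the minimum credible event
#'   duration from surrogate (bin-shuffled) data
#' @param p1_factor the clamped low state emits one spike with probability
#'   `p1_factor * mean(counts)` (and never more than one)
#' @param max_iter,tol Baum-Welch iteration cap and relative log-likelihood
#'   convergence tolerance
#' @param n_surrogates number of independent bin shufflings pooled for the
#'   duration calibration
#' @param conditional_tail if `TRUE`, the surrogate exponential tail is read
#'   as conditional on exceeding its 75th percentile; the default treats the
#'   fitted tail as unconditional over all surrogate events
#' @param seed seed for the surrogate shuffling (`NULL` = current RNG state)
#' @return an object of class `detector_config`
#' @export
detector_config <- function(mode = c("ns_quasiorbit", "avalanche"),
                            dt_bin = NULL, P_surrogate = 1e-3,
                            p1_factor = 1e-6, max_iter = 300L, tol = 1e-8,
                            n_surrogates = 1L, conditional_tail = FALSE,
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(P_surrogate >= 1e-4, P_surrogate <= 1e-2,
            p1_factor >= 1e-8, p1_factor <= 1e-4,
            max_iter >= 1, tol > 0, n_surrogates >= 1)
  structure(list(mode = mode, dt_bin = dt_bin, P_surrogate = P_surrogate,
                 p1_factor = p1_factor, max_iter = as.integer(max_iter),
                 tol = tol, n_surrogates = as.integer(n_surrogates),
                 conditional_tail = isTRUE(conditional_tail), seed = seed),
            class = "detector_config")
}

hmm_init_rates <- function(counts) {
  q5 <- quantile(counts, 0.5, names = FALSE)
  q9 <- quantile(counts, 0.9, names = FALSE)
  lam0 <- mean(counts[counts <= q5])
  # a zero low-state rate is absorbing under EM (it can never re-estimate
  # away from zero once any nonzero bin is forced into the high state)
  lam0 <- max(lam0, 0.05 * mean(counts), 1e-6)
  hi <- counts[counts > q9]
  lam1 <- if (length(hi)) mean(hi) else max(mean(counts), lam0 + 1)
  if (lam1 <= lam0) lam1 <- lam0 + max(1, lam0)
  c(lam0, lam1)
}

#' Fit the two-state hidden-Markov model to a count series
#'
#' Baum-Welch estimation of a two-state chain with Poisson emissions (low /
#' high activity).  Initialisation: low rate = mean of counts below their
#' median, high rate = mean above the 90th percentile, sticky transitions
#' (0.99 stay).  In avalanche mode the low state's emission table is kept
#' clamped throughout re-estimation to
#' `p(1) = p1_factor * mean(counts)`, `p(0) = 1 - p(1)`, `p(n >= 2) = 0`;
#' only its transitions and the high state are updated.
#'
#' @param series a [count_series()]
#' @param cfg a [detector_config()]
#' @return object of class `hmm_two_state`: list with `lambda` (low, high
#'   emission rates per bin), `trans` (2x2 row-stochastic), `init`,
#'   `loglik` (per-iteration trace), `converged`, `clamp`, `p1`
#' @export
fit_hmm <- function(series, cfg) {
  stopifnot(inherits(series, "count_series"), inherits(cfg, "detector_config"))
  counts <- series$counts
  if (length(counts) < 1000)
    stop("fit_hmm: need at least 1000 bins")
  clamp <- cfg$mode == "avalanche"
  if (sd(counts) == 0 && !clamp)
    warning("fit_hmm: constant series; both states collapse onto the same rate")
  lam <- hmm_init_rates(counts)
  p1 <- if (clamp) cfg$p1_factor * mean(counts) else 0
  fit <- .hmm_baum_welch_cpp(counts, lam[1], lam[2], 0.99, 0.99, clamp, p1,
                             cfg$max_iter, cfg$tol)
  # keep states sorted: high-state emission mean >= low-state
  if (!clamp && fit$lambda[2] < fit$lambda[1]) {
    fit$lambda <- rev(fit$lambda)
    fit$init <- rev(fit$init)
    fit$trans <- fit$trans[2:1, 2:1]
  }
  if (!fit$converged)
    warning("fit_hmm: Baum-Welch did not converge within max_iter; ",
            "best iterate returned")
  structure(list(lambda = fit$lambda, trans = fit$trans, init = fit$init,
                 loglik = fit$loglik, converged = fit$converged,
                 clamp = clamp, p1 = p1),
            class = "hmm_two_state")
}

#' Most probable hidden-state path
#'
#' Viterbi decoding (log-space, safe for arbitrarily long series) of the
#' fitted two-state model; 0 = low activity, 1 = high activity (network
#' event).
#'
#' @param series a [count_series()]
#' @param hmm a fitted [fit_hmm()] model
#' @return integer vector of 0/1 states, one per bin
#' @export
decode_states <- function(series, hmm) {
  stopifnot(inherits(series, "count_series"), inherits(hmm, "hmm_two_state"))
  if (!length(series$counts)) return(integer(0))
  .hmm_viterbi_cpp(series$counts, hmm$lambda[1], hmm$lambda[2], hmm$trans,
                   hmm$init, hmm$clamp, hmm$p1)
}

run_lengths_high <- function(path) {
  r <- rle(path)
  r$lengths[r$values == 1L]
}

#' Minimum event duration from the surrogate-duration decision rule
#'
#' Given high-state run durations decoded from a bin-shuffled surrogate
#' series, fits a shifted exponential to the exceedances above the 75th
#' percentile `q75` (maximum-likelihood mean exceedance `tau_hat`) and
#' returns the duration whose tail probability equals `P`:
#' `d* = q75 + tau_hat * log(0.25 / P)` under the unconditional reading
#' (`P(D > d*) = P` over all surrogate events), or
#' `d* = q75 + tau_hat * log(1 / P)` under the conditional one.
#'
#' @param durations surrogate event durations (ms)
#' @param P tail probability
#' @param conditional tail probability conditional on exceeding `q75`?
#' @return duration threshold (ms)
#' @export
duration_threshold <- function(durations, P, conditional = FALSE) {
  stopifnot(P > 0, P <= 0.25 || conditional)
  if (length(durations) < 20) {
    warning("duration_threshold: fewer than 20 surrogate events; ",
            "falling back to the longest surrogate duration")
    return(max(durations, 0))
  }
  q75 <- quantile(durations, 0.75, names = FALSE)
  exc <- durations[durations > q75] - q75
  tau_hat <- if (length(exc)) mean(exc) else 0
  q75 + tau_hat * log(if (conditional) 1 / P else 0.25 / P)
}

#' Surrogate-calibrated minimum event duration
#'
#' Shuffles the bins of the series (destroying temporal structure while
#' preserving the count distribution), decodes it with the fitted model,
#' and applies [duration_threshold()] to the durations of the decoded
#' high-state runs.
#'
#' @param series a [count_series()]
#' @param hmm fitted model from [fit_hmm()]
#' @param cfg a [detector_config()] (`ns_quasiorbit` mode)
#' @return duration threshold (ms)
#' @export
surrogate_min_duration <- function(series, hmm, cfg) {
  stopifnot(cfg$mode == "ns_quasiorbit")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  durs <- unlist(lapply(seq_len(cfg$n_surrogates), function(i) {
    shuffled <- count_series(sample(series$counts), series$dt_bin)
    run_lengths_high(decode_states(shuffled, hmm)) * series$dt_bin
  }))
  duration_threshold(durs, cfg$P_surrogate, cfg$conditional_tail)
}

#' Detect network events in a count series
#'
#' The unified two-step procedure: (1) fit the two-state HMM by Baum-Welch;
#' (2) Viterbi-decode and take maximal runs of the high state as events.
#' In `ns_quasiorbit` mode only runs at least as long as the
#' surrogate-calibrated minimum duration are kept (labels are assigned later
#' by [classify_events()]); in `avalanche` mode every high-state run is an
#' event, with no duration or size threshold.
#'
#' @param series a [count_series()]
#' @param cfg a [detector_config()]
#' @return object of class `event_list`: data frame with columns
#'   `onset_bin`, `offset_bin` (0-based, half-open), `onset_ms`,
#'   `duration_ms`, `size` (total spikes in the event), `peak` (maximum bin
#'   count) and `label`; attributes carry the fitted model, the duration
#'   threshold and the configuration
#' @export
detect_events <- function(series, cfg) {
  stopifnot(inherits(series, "count_series"), inherits(cfg, "detector_config"))
  empty <- data.frame(onset_bin = integer(0), offset_bin = integer(0),
                      onset_ms = numeric(0), duration_ms = numeric(0),
                      size = numeric(0), peak = integer(0),
                      label = character(0))
  if (!length(series$counts))
    return(structure(empty, class = c("event_list", "data.frame"),
                     dt_bin = series$dt_bin, threshold_ms = NA_real_))
  hmm <- fit_hmm(series, cfg)
  thr <- NA_real_
  if (!hmm$clamp && diff(hmm$lambda) < 1e-10) {
    ev <- empty  # degenerate fit: no separable high-activity state
  } else {
    path <- decode_states(series, hmm)
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values == 1L
    onset <- starts[keep] - 1L   # 0-based
    offset <- ends[keep]         # half-open
    if (cfg$mode == "ns_quasiorbit") {
      thr <- surrogate_min_duration(series, hmm, cfg)
      long_enough <- (offset - onset) * series$dt_bin >= thr
      onset <- onset[long_enough]
      offset <- offset[long_enough]
    }
    cs <- cumsum(c(0, series$counts))
    size <- cs[offset + 1L] - cs[onset + 1L]
    peak <- vapply(seq_along(onset), function(i)
      max(series$counts[(onset[i] + 1L):offset[i]]), integer(1))
    ev <- data.frame(onset_bin = onset, offset_bin = offset,
                     onset_ms = series$t0 + onset * series$dt_bin,
                     duration_ms = (offset - onset) * series$dt_bin,
                     size = size, peak = peak,
                     label = if (length(onset))
                       ifelse(cfg$mode == "avalanche", "AVALANCHE",
                              "UNLABELED") else character(0))
  }
  structure(ev, class = c("event_list", "data.frame"),
            dt_bin = series$dt_bin, threshold_ms = thr, hmm = hmm,
            config = cfg)
}
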