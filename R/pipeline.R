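#' Detect and classify network events in a simulated trace
#'
#' Pools the per-step spike counts, rebins them to the detector bin width,
#' runs the two-state HMM detector, and (when at least `min_events` events
#' are found) fits the size mixture and labels events as network spikes or
#' quasi-orbits.
#'
#' @param trace a `trace_set` from [simulate_network()]
#' @param dt_bin detector bin width (ms)
#' @param cfg optional [detector_config()] (defaults to `ns_quasiorbit`
#'   with the given `dt_bin`)
#' @param classify fit the size mixture and label events?
#' @param min_events minimum number of events required for the mixture fit
#' @return list with `series`, `events`, and (if classified) `mixture`
#' @export
detect_network_events <- function(trace, dt_bin = 4, cfg = NULL,
                                  classify = TRUE, min_events = 50) {
  series <- trace_count_series(trace, dt_bin)
  if (is.null(cfg)) cfg <- detector_config("ns_quasiorbit", dt_bin = dt_bin)
  events <- detect_events(series, cfg)
  mixture <- NULL
  if (classify && nrow(events) >= min_events) {
    mixture <- tryCatch(fit_size_mixture(events$size), error = function(e) NULL)
    if (!is.null(mixture)) events <- classify_events(events, mixture)
  }
  list(series = series, events = events, mixture = mixture)
}

#' Simulate one working point and infer its effective fatigue timescale
#'
#' Runs the stochastic model at a given `(w_exc, w_inh)`, detects network
#' spikes and quasi-orbits, and scans candidate integrator timescales for
#' the (negative) peak of the correlation between the low-pass-filtered
#' rate and the event size.  Both event families enter the scan.
#'
#' @param p a [network_params()] object; `w_exc`/`w_inh` are overridden
#'   when `w` is given
#' @param w optional `c(w_exc, w_inh)`
#' @param minutes simulated minutes recorded after burn-in
#' @param seed RNG seed for the run
#' @param dt_bin detector bin width (ms)
#' @param tau_grid scan grid (s)
#' @param B permutations for the significance bound
#' @return list with `w`, `stability`, `mean_rate_Hz` (mean of the pooled
#'   per-neuron count rate, the observable that also drives the fatigue
#'   integrator), `mean_rate_E_Hz`, `n_events`,
#'   `tau_opt_s` (deepest significant scan minimum, `NA` when none),
#'   `scan`, `events`
#' @export
run_working_point <- function(p, w = NULL, minutes = 20, seed = 1,
                              dt_bin = 4,
                              tau_grid = 10^seq(log10(0.05), log10(10),
                                                length.out = 40),
                              B = 400) {
  if (!is.null(w)) {
    p$w_exc <- w[1]
    p$w_inh <- w[2]
  }
  st <- stability_analysis(p)
  cfg <- sim_config(duration = minutes * 60000, seed = seed)
  trace <- simulate_network(p, cfg, init = as.numeric(st$fixed_point))
  det <- detect_network_events(trace, dt_bin = dt_bin, classify = FALSE)
  rate_Hz <- det$series$counts / ((p$n_E + p$n_I) * dt_bin / 1000)
  out <- list(w = c(p$w_exc, p$w_inh), stability = st,
              mean_rate_Hz = mean(rate_Hz),
              mean_rate_E_Hz = 1000 * mean(trace$states[, "nu_E"]),
              n_events = nrow(det$events),
              tau_opt_s = NA_real_, scan = NULL, events = det$events)
  if (nrow(det$events) >= 30) {
    scan <- correlation_scan(rate_Hz, dt_bin / 1000, det$events,
                             tau_grid = tau_grid, B = B)
    out$scan <- scan
    if (nrow(scan$optima))
      out$tau_opt_s <- scan$optima$tau_star_opt[which.min(scan$optima$correlation)]
  }
  out
}

#' Recover the depression parameters across several working points
#'
#' Repeats [run_working_point()] at a set of working points spanning the
#' oscillatory region of the excitation-inhibition plane (both sides of
#' the Hopf line, so that mean rates cover a wide range), collects the
#' (mean observed rate, optimal timescale) pairs, and fits the
#' effective-timescale relation to recover the depression recovery time
#' and utilisation fraction.
#'
#' @param p a [network_params()] object (the depression truth to recover)
#' @param points two-column matrix or data frame of `(w_exc, w_inh)` points
#' @param minutes simulated minutes per point
#' @param seed base seed; point `i` uses `seed + i`
#' @param ... passed on to [run_working_point()]
#' @return list with `recovery` (a [fit_std_params()] result), `points`
#'   (per-point summaries), `used` (logical: point entered the fit)
#' @export
run_timescale_study <- function(p, points = NULL, minutes = 20, seed = 1,
                                ...) {
  if (is.null(points))
    points <- rbind(c(0.82, 0.55), c(0.88, 1.00), c(0.90, 1.00),
                    c(0.94, 1.00), c(0.99, 1.00), c(1.02, 1.00),
                    c(1.10, 0.90), c(1.20, 0.40), c(1.40, 0.35))
  points <- as.matrix(points)
  res <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    res[[i]] <- run_working_point(p, w = points[i, ], minutes = minutes,
                                  seed = seed + i, ...)
  }
  rates <- vapply(res, `[[`, 0, "mean_rate_Hz")
  taus <- vapply(res, `[[`, 0, "tau_opt_s")
  used <- is.finite(taus)
  recovery <- fit_std_params(rates[used], taus[used])
  list(recovery = recovery, points = res, used = used)
}

#' Avalanche size distribution at one working point
#'
#' Simulates the model, detects avalanches with the clamped-low-state HMM
#' variant at the integration resolution, and fits a power law to the
#' avalanche sizes.
#'
#' @param p a [network_params()] object
#' @param w optional `c(w_exc, w_inh)`
#' @param minutes simulated minutes
#' @param seed RNG seed
#' @param dt_bin detector bin width (ms); the integration step by default
#' @return list with `events`, `fit` (a [fit_power_law()] result),
#'   `n_events`, `decades` (log10 span of the fitted tail)
#' @export
run_avalanche_study <- function(p, w = NULL, minutes = 20, seed = 1,
                                dt_bin = NULL) {
  if (!is.null(w)) {
    p$w_exc <- w[1]
    p$w_inh <- w[2]
  }
  cfg <- sim_config(duration = minutes * 60000, seed = seed)
  trace <- simulate_network(p, cfg)
  if (is.null(dt_bin)) dt_bin <- trace$dt
  series <- trace_count_series(trace, dt_bin)
  det_cfg <- detector_config("avalanche", dt_bin = dt_bin)
  events <- detect_events(series, det_cfg)
  fit <- fit_power_law(events$size)
  tail_max <- max(events$size[events$size >= fit$xmin])
  list(events = events, fit = fit, n_events = nrow(events),
       decades = log10(tail_max / fit$xmin))
}
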