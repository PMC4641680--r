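#' Simulation configuration
#'
#' @param duration simulated time to record (ms)
#' @param dt integration step (ms); the stochastic dynamics is integrated
#'   with a fixed explicit-Euler step
#' @param seed RNG seed applied at the start of the run (`NULL` = leave the
#'   RNG state untouched)
#' @param record_stride decimation factor for the recorded state trajectory
#'   (spike counts are always kept at full resolution)
#' @param burn_in simulated time discarded before recording starts (ms)
#' @param noise if `FALSE`, the per-step Poisson counts are replaced by
#'   their expectations, giving the deterministic mean-field trajectory
#' @param phi_tol relative tolerance of the transfer-function quadrature
#'   used inside the integrator
#' @return an object of class `sim_config`
#' @export
sim_config <- function(duration, dt = 0.25, seed = NULL, record_stride = 1L,
                       burn_in = 10000, noise = TRUE, phi_tol = 1e-8) {
  stopifnot(dt > 0, duration >= dt, burn_in >= 0, record_stride >= 1)
  structure(list(duration = duration, dt = dt, seed = seed,
                 record_stride = as.integer(record_stride),
                 burn_in = burn_in, noise = isTRUE(noise),
                 phi_tol = phi_tol),
            class = "sim_config")
}

#' One finite-size Poisson sample of a population rate
#'
#' The spike count emitted by `n` neurons firing at rate `nu` in a bin of
#' width `dt` is Poisson with mean `n * nu * dt`; the empirical rate
#' `count / (n * dt)` is an unbiased, noisy version of `nu` with variance
#' `nu / (n * dt)` -- the finite-size noise entering the synaptic filters.
#'
#' @param nu population rate (kHz); vectorised
#' @param n number of neurons
#' @param dt bin width (ms)
#' @return list with integer `count` and `nu_n = count / (n dt)` (kHz)
#' @export
poisson_rate_sample <- function(nu, n, dt) {
  if (any(nu < 0)) stop("poisson_rate_sample: nu must be nonnegative")
  stopifnot(n >= 1, dt > 0)
  count <- rpois(length(nu), n * nu * dt)
  list(count = count, nu_n = count / (n * dt))
}

#' Simulate the stochastic rate model
#'
#' Integrates the five-dimensional (seven with adaptation) noisy mean-field
#' dynamics with a fixed explicit-Euler step.  At each step the spike count
#' of each population is drawn as a Poisson variable with mean `n nu dt`;
#' the resulting empirical rates drive the synaptic filters, the resource
#' depletion, and the adaptation integrator.  The trajectory starts at the
#' deterministic fixed point (computed via [find_fixed_point()] unless
#' `init` is given) and a burn-in period is discarded before recording.
#'
#' @param p a [network_params()] object
#' @param cfg a [sim_config()] object
#' @param init optional initial state, a numeric vector
#'   `(nu_E, nu_I, nu_tilde_E, nu_tilde_I, r_E, c_E)` (kHz / dimensionless)
#' @return an object of class `trace_set`: list with `time` (ms, decimated),
#'   `states` (matrix with columns `nu_E, nu_I, nu_tilde_E, nu_tilde_I,
#'   r_E, c_E`), `count_E`, `count_I`, `count_total` (per-step spike counts
#'   at full `dt` resolution), `dt`, `params`, `config`
#' @export
simulate_network <- function(p, cfg, init = NULL) {
  stopifnot(inherits(p, "network_params"), inherits(cfg, "sim_config"))
  if (is.null(init)) {
    fp <- find_fixed_point(p)
    init <- as.numeric(fp)
  }
  stopifnot(length(init) == 6, all(is.finite(init)))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  par <- unlist(p[c("n_E", "n_I", "c", "J_EE", "sigma_J_EE", "J_IE",
                    "sigma_J_IE", "J_EI", "sigma_J_EI", "J_II", "sigma_J_II",
                    "J_ext", "sigma_J_ext", "nu_ext", "tau_E", "tau_I",
                    "tau_filter_E", "tau_filter_I", "tau_STD", "u_STD",
                    "g_SFA", "tau_SFA", "w_exc", "w_inh", "tau_V",
                    "tau_refract", "V_rest", "V_reset", "V_thresh")])
  out <- .sim_network_cpp(par, init, cfg$duration, cfg$dt, cfg$burn_in,
                          cfg$record_stride, cfg$noise, cfg$phi_tol)
  colnames(out$states) <- c("nu_E", "nu_I", "nu_tilde_E", "nu_tilde_I",
                            "r_E", "c_E")
  structure(list(time = out$time, states = out$states,
                 count_E = out$count_E, count_I = out$count_I,
                 count_total = out$count_E + out$count_I,
                 dt = cfg$dt, params = p, config = cfg),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %.1f s recorded at dt = %g ms (%d count bins, %d state samples)\n",
              length(x$count_E) * x$dt / 1000, x$dt, length(x$count_E),
              length(x$time)))
  cat(sprintf("  mean rates: nu_E = %.3f Hz, nu_I = %.3f Hz; mean r_E = %.3f\n",
              1000 * mean(x$states[, "nu_E"]), 1000 * mean(x$states[, "nu_I"]),
              mean(x$states[, "r_E"])))
  invisible(x)
}

#' Pooled spike-count series of a simulated trace
#'
#' Pools the excitatory and inhibitory per-step counts (mirroring pooled
#' multielectrode channels) and optionally rebins to a coarser bin width.
#'
#' @param trace a `trace_set`
#' @param dt_bin target bin width (ms); must be an integer multiple of the
#'   integration step
#' @param population `"total"`, `"E"` or `"I"`
#' @return a [count_series()] object
#' @export
trace_count_series <- function(trace, dt_bin = trace$dt,
                               population = c("total", "E", "I")) {
  population <- match.arg(population)
  counts <- switch(population, total = trace$count_total,
                   E = trace$count_E, I = trace$count_I)
  ser <- count_series(as.integer(round(counts)), dt_bin = trace$dt)
  if (dt_bin != trace$dt) {
    k <- dt_bin / trace$dt
    if (abs(k - round(k)) > 1e-8)
      stop("dt_bin must be an integer multiple of the simulation step")
    ser <- rebin_counts(ser, as.integer(round(k)))
  }
  ser
}

#' Export a simulated trace as a tab-separated table
#'
#' Writes the decimated state trajectory together with the spike counts
#' accumulated over each recorded interval.  A commented header carries the
#' full parameter set and seed for provenance.
#'
#' @param trace a `trace_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  stride <- trace$config$record_stride
  n <- length(trace$time)
  agg <- function(v) {
    idx <- ceiling(seq_along(v) / stride)
    as.numeric(tapply(v, idx, sum))[seq_len(n)]
  }
  df <- data.frame(time_ms = trace$time,
                   nu_E_Hz = 1000 * trace$states[, "nu_E"],
                   nu_I_Hz = 1000 * trace$states[, "nu_I"],
                   r_E = trace$states[, "r_E"],
                   c_E = trace$states[, "c_E"],
                   count_E = agg(trace$count_E),
                   count_I = agg(trace$count_I))
  df$count_total <- df$count_E + df$count_I
  con <- file(path, "w")
  on.exit(close(con))
  prm <- unclass(trace$params)
  writeLines(c(sprintf("# netevents trace; dt_ms=%g record_stride=%d seed=%s",
                       trace$dt, stride,
                       ifelse(is.null(trace$config$seed), "NA",
                              trace$config$seed)),
               paste0("# params: ",
                      paste(names(prm), unlist(prm), sep = "=",
                            collapse = " "))), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Advance the network state by one Euler step
#'
#' Single explicit-Euler update of the full stochastic state, drawing one
#' Poisson spike count per population (or using the expected counts when
#' `noise = FALSE`).  [simulate_network()] runs the same update in compiled
#' code; this R-level version exposes the elementary transition for
#' inspection and testing.
#'
#' @param state numeric vector `(nu_E, nu_I, nu_tilde_E, nu_tilde_I, r_E,
#'   c_E)` (rates kHz)
#' @param p a [network_params()] object
#' @param dt step (ms)
#' @param noise draw finite-size Poisson counts?
#' @return list with `state` (updated, clipped to the physical domain) and
#'   `counts` (`c(E, I)`)
#' @export
step_network <- function(state, p, dt = 0.25, noise = TRUE) {
  stopifnot(length(state) == 6, all(is.finite(state)))
  m <- current_moments(state[3], state[4], state[5], p, c_SFA = state[6])
  tp <- transfer_of(p)
  phiE <- lif_phi(m$mu_E, m$sigma2_E, tp, tol = 1e-8)
  phiI <- lif_phi(m$mu_I, m$sigma2_I, tp, tol = 1e-8)
  if (noise) {
    sE <- poisson_rate_sample(state[1], p$n_E, dt)
    sI <- poisson_rate_sample(state[2], p$n_I, dt)
    nu_nE <- sE$nu_n; nu_nI <- sI$nu_n
    counts <- c(E = sE$count, I = sI$count)
  } else {
    nu_nE <- state[1]; nu_nI <- state[2]
    counts <- c(E = p$n_E * state[1] * dt, I = p$n_I * state[2] * dt)
  }
  new <- c(state[1] + dt / p$tau_E * (phiE - state[1]),
           state[2] + dt / p$tau_I * (phiI - state[2]),
           state[3] + dt / p$tau_filter_E * (nu_nE - state[3]),
           state[4] + dt / p$tau_filter_I * (nu_nI - state[4]),
           state[5] + dt * ((1 - state[5]) / p$tau_STD -
                              p$u_STD * state[5] * state[3]),
           state[6] + dt / p$tau_SFA * (nu_nE - state[6]))
  if (any(!is.finite(new)))
    stop("step_network: simulation diverged (non-finite state)")
  new[1:4] <- pmax(new[1:4], 0)
  new[5] <- min(max(new[5], 0), 1)
  new[6] <- max(new[6], 0)
  names(new) <- c("nu_E", "nu_I", "nu_tilde_E", "nu_tilde_I", "r_E", "c_E")
  list(state = new, counts = counts)
}
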