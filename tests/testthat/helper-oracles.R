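# Independent oracles used across the suite.  These deliberately avoid the
# package's own numerical paths (C++ quadrature, scaled forward-backward,
# recursive filters) so that agreement is evidence, not tautology.

# --- LIF transfer function via stats::integrate + pracma's scaled erfc ----
phi_quadrature_oracle <- function(mu, sigma2, p = transfer_params()) {
  a <- (p$V_reset - p$V_rest - mu * p$tau_V) / sqrt(sigma2 * p$tau_V)
  b <- (p$V_thresh - p$V_rest - mu * p$tau_V) / sqrt(sigma2 * p$tau_V)
  I <- stats::integrate(function(s) pracma::erfcx(-s), a, b,
                        rel.tol = 1e-13, abs.tol = 0)$value
  1 / (sqrt(pi) * p$tau_V * I + p$tau_refract)
}

# --- exhaustive-enumeration HMM oracle (tiny T only) ----------------------
hmm_emission_prob <- function(state, count, lambda, clamp = FALSE, p1 = 0) {
  if (state == 0 && clamp) {
    if (count == 0) return(1 - p1)
    if (count == 1) return(p1)
    return(0)
  }
  dpois(count, lambda[state + 1])
}

hmm_enumerate <- function(counts, lambda, trans, init, clamp = FALSE,
                          p1 = 0) {
  T_ <- length(counts)
  paths <- as.matrix(expand.grid(rep(list(0:1), T_)))
  best <- -Inf; best_path <- NULL; total <- 0
  for (i in seq_len(nrow(paths))) {
    s <- as.integer(paths[i, ])
    pr <- init[s[1] + 1] * hmm_emission_prob(s[1], counts[1], lambda, clamp, p1)
    if (T_ > 1) for (t in 2:T_) {
      pr <- pr * trans[s[t - 1] + 1, s[t] + 1] *
        hmm_emission_prob(s[t], counts[t], lambda, clamp, p1)
    }
    total <- total + pr
    if (pr > best) { best <- pr; best_path <- s }
  }
  list(loglik = log(total), best_path = best_path, best_logprob = log(best))
}

# --- fine-step Euler oracle for the fatigue integrator --------------------
fatigue_euler_oracle <- function(rate, dt, tau_star, f0 = 0, refine = 100) {
  f <- f0
  out <- numeric(length(rate))
  h <- dt / refine
  for (k in seq_along(rate)) {
    out[k] <- f
    for (i in seq_len(refine)) f <- f + h * (-f / tau_star + rate[k])
  }
  out
}

# --- small helpers --------------------------------------------------------
expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}

# deterministic fixed point as a plain numeric vector
fp_vector <- function(p) as.numeric(find_fixed_point(p))
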