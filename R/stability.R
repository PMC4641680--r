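#' Deterministic drift of the mean-field dynamics
#'
#' Right-hand side of the noise-free rate equations (finite-size noise
#' replaced by its mean), used for fixed points, linearisation, and the
#' convergence diagnostics of the simulator.
#'
#' @param state numeric vector `(nu_E, nu_I, nu_tilde_E, nu_tilde_I, r_E,
#'   c_E)`; rates in kHz
#' @param p a [network_params()] object
#' @param phi_tol transfer-function quadrature tolerance
#' @return time derivative of the state (per ms)
#' @export
deterministic_drift <- function(state, p, phi_tol = 1e-10) {
  m <- current_moments(state[3], state[4], state[5], p, c_SFA = state[6])
  tp <- transfer_of(p)
  phiE <- lif_phi(m$mu_E, m$sigma2_E, tp, tol = phi_tol)
  phiI <- lif_phi(m$mu_I, m$sigma2_I, tp, tol = phi_tol)
  c((phiE - state[1]) / p$tau_E,
    (phiI - state[2]) / p$tau_I,
    (state[1] - state[3]) / p$tau_filter_E,
    (state[2] - state[4]) / p$tau_filter_I,
    (1 - state[5]) / p$tau_STD - p$u_STD * state[5] * state[3],
    (state[1] - state[6]) / p$tau_SFA)
}

fp_state <- function(nu, p) {
  r <- 1 / (1 + p$u_STD * nu[1] * p$tau_STD)
  c(nu_E = nu[1], nu_I = nu[2], nu_tilde_E = nu[1], nu_tilde_I = nu[2],
    r_E = r, c_E = nu[1])
}

# residual of the 2-D self-consistency nu = Phi(mu(nu), sigma2(nu))
fp_residual <- function(nu, p, phi_tol = 1e-12) {
  st <- fp_state(nu, p)
  m <- current_moments(st[3], st[4], st[5], p, c_SFA = st[6])
  tp <- transfer_of(p)
  c(lif_phi(m$mu_E, m$sigma2_E, tp, tol = phi_tol) - nu[1],
    lif_phi(m$mu_I, m$sigma2_I, tp, tol = phi_tol) - nu[2])
}

newton_2d <- function(f, x0, tol = 1e-15, max_iter = 100) {
  x <- x0
  for (i in seq_len(max_iter)) {
    Fx <- f(x)
    if (!all(is.finite(Fx))) return(NULL)
    if (max(abs(Fx)) < tol) return(x)
    h <- pmax(abs(x), 1e-4) * 1e-7
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      hj <- if (x[j] - h[j] < 0) x[j] / 2 else h[j]
      xp <- x; xm <- x
      if (hj > 0) {
        xp[j] <- x[j] + hj; xm[j] <- x[j] - hj
        J[, j] <- (f(xp) - f(xm)) / (2 * hj)
      } else {
        xp[j] <- x[j] + h[j]
        J[, j] <- (f(xp) - Fx) / h[j]
      }
    }
    dx <- tryCatch(solve(J, Fx), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    step <- 1
    repeat {
      xn <- pmax(x - step * dx, 0)
      Fn <- f(xn)
      if (all(is.finite(Fn))) break
      step <- step / 2
      if (step < 1e-8) return(NULL)
    }
    x <- xn
  }
  if (max(abs(f(x))) < 1e-12) x else NULL
}

#' Deterministic fixed point of the mean-field model
#'
#' Solves the self-consistency \eqn{\nu_E = \Phi(\mu_E, \sigma^2_E)},
#' \eqn{\nu_I = \Phi(\mu_I, \sigma^2_I)} with filtered rates equal to the
#' rates, depression at its activity-dependent steady state
#' \eqn{r_E = 1/(1 + u_{STD}\,\nu_E\,\tau_{STD})}, and (when adaptation is
#' enabled) \eqn{c_E = \nu_E}.  A Newton multistart over
#' \eqn{\nu_E \in \{0.1, 1, 5, 20, 100\}} Hz is used and the low-activity
#' root (smallest converged \eqn{\nu_E}) is returned.
#'
#' @param p a [network_params()] object
#' @return named numeric state vector of class `network_state`
#' @export
find_fixed_point <- function(p) {
  stopifnot(inherits(p, "network_params"))
  f <- function(nu) fp_residual(nu, p)
  roots <- list()
  for (start in c(1e-4, 1e-3, 5e-3, 2e-2, 1e-1)) {
    x <- newton_2d(f, c(start, start))
    if (!is.null(x)) roots[[length(roots) + 1]] <- x
  }
  if (!length(roots)) stop("find_fixed_point: no root converged")
  nu <- roots[[which.min(vapply(roots, `[`, 0, 1))]]
  st <- fp_state(nu, p)
  res <- deterministic_drift(st, p)
  if (sqrt(sum(res^2)) > 1e-10)
    stop("find_fixed_point: converged root fails the drift residual check")
  structure(st, class = "network_state")
}

#' Jacobian of the deterministic dynamics at a fixed point
#'
#' Central finite differences of [deterministic_drift()] with Richardson
#' extrapolation, step `h` relative to each variable's natural scale.  The
#' adaptation dimension is included only when `g_SFA > 0` (the adaptation
#' variable is otherwise dynamically irrelevant), giving a 5x5 or 6x6
#' matrix.
#'
#' @param p a [network_params()] object
#' @param fp fixed point from [find_fixed_point()]
#' @param h base finite-difference step (relative)
#' @param richardson use Richardson extrapolation of the central difference
#' @return Jacobian matrix (units 1/ms)
#' @export
network_jacobian <- function(p, fp, h = 1e-5, richardson = TRUE) {
  dims <- if (p$g_SFA > 0) 6L else 5L
  scales <- pmax(abs(fp[seq_len(dims)]), 1e-3)
  J <- matrix(0, dims, dims)
  drift_d <- function(x) {
    st <- c(x, if (dims == 5L) fp[6] else NULL)
    deterministic_drift(st, p)[seq_len(dims)]
  }
  x0 <- as.numeric(fp[seq_len(dims)])
  for (j in seq_len(dims)) {
    cd <- function(hj) {
      xp <- x0; xm <- x0
      xp[j] <- x0[j] + hj; xm[j] <- x0[j] - hj
      (drift_d(xp) - drift_d(xm)) / (2 * hj)
    }
    hj <- h * scales[j]
    # keep rate perturbations nonnegative (one-sided shrink near zero)
    if (j <= 4 && x0[j] - hj < 0) hj <- x0[j] / 2
    if (hj <= 0) {  # variable pinned at zero: forward difference
      hj <- h * scales[j]
      fd <- function(hh) {
        xp <- x0; xp[j] <- x0[j] + hh
        (drift_d(xp) - drift_d(x0)) / hh
      }
      J[, j] <- if (richardson) (4 * fd(hj / 2) - fd(hj)) / 3 else fd(hj)
    } else {
      J[, j] <- if (richardson) (4 * cd(hj / 2) - cd(hj)) / 3 else cd(hj)
    }
  }
  if (any(!is.finite(J)))
    stop("network_jacobian: non-finite entries in the finite-difference Jacobian")
  rn <- c("nu_E", "nu_I", "nu_tilde_E", "nu_tilde_I", "r_E", "c_E")[seq_len(dims)]
  dimnames(J) <- list(rn, rn)
  J
}

#' Linear stability analysis at a working point
#'
#' Fixed point, Jacobian and eigenvalue spectrum of the linearised
#' deterministic dynamics.  Eigenvalues are sorted by descending real part
#' (ties broken by larger imaginary magnitude); the dominant pair's real and
#' imaginary parts are reported in Hz (1/s; internal time is ms, conversion
#' factor 1000).
#'
#' @param p a [network_params()] object
#' @return object of class `stability_result`: list with `fixed_point`,
#'   `jacobian`, `eigenvalues` (complex, 1/ms), `re_lambda`, `im_lambda`
#'   (Hz), `is_oscillatory`
#' @export
stability_analysis <- function(p) {
  fp <- find_fixed_point(p)
  J <- network_jacobian(p, fp)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev), -abs(Im(ev)))]
  dom <- ev[1]
  structure(list(fixed_point = fp, jacobian = J, eigenvalues = ev,
                 re_lambda = Re(dom) * 1000, im_lambda = abs(Im(dom)) * 1000,
                 is_oscillatory = abs(Im(dom)) > 0),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability_result: nu_E = %.3f Hz, nu_I = %.3f Hz, r_E = %.3f\n",
              1000 * x$fixed_point[1], 1000 * x$fixed_point[2],
              x$fixed_point[5]))
  cat(sprintf("  dominant eigenvalue: Re = %.3f Hz, Im = %.3f Hz (%s)\n",
              x$re_lambda, x$im_lambda,
              ifelse(x$is_oscillatory, "oscillatory", "non-oscillatory")))
  invisible(x)
}

#' Stability map over the excitation-inhibition plane
#'
#' Computes the fixed point and dominant eigenvalue on a grid of
#' `(w_exc, w_inh)` scale factors.  Cells where no fixed point is found are
#' marked `NA` without aborting the sweep.  Iso-lines of the dominant real
#' part (by default at -3.5, 0 and +3.5 Hz; the 0 Hz line is the Hopf
#' bifurcation) are extracted from the interpolated map.
#'
#' @param p a [network_params()] object (its `w_exc`, `w_inh` are ignored)
#' @param w_exc,w_inh strictly increasing grid vectors
#' @param levels iso-line levels for the real part (Hz)
#' @return object of class `plane_map`: list with the grids, matrices
#'   `re_lambda`, `im_lambda` (Hz), `rate_E` (Hz), and `contours` (list of
#'   data frames with `w_exc`, `w_inh`, `level`)
#' @export
plane_sweep <- function(p, w_exc = seq(0.4, 1.4, by = 0.1),
                        w_inh = seq(0.3, 1.5, by = 0.1),
                        levels = c(-3.5, 0, 3.5)) {
  stopifnot(all(diff(w_exc) > 0), all(diff(w_inh) > 0))
  nx <- length(w_exc); ny <- length(w_inh)
  re <- im <- rate <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      pij <- p
      pij$w_exc <- w_exc[i]
      pij$w_inh <- w_inh[j]
      s <- tryCatch(stability_analysis(pij), error = function(e) NULL)
      if (!is.null(s)) {
        re[i, j] <- s$re_lambda
        im[i, j] <- s$im_lambda
        rate[i, j] <- 1000 * s$fixed_point[1]
      }
    }
  }
  contours <- list()
  if (!all(is.na(re))) {
    cl <- contourLines(w_exc, w_inh, re, levels = levels)
    contours <- lapply(cl, function(ln)
      data.frame(w_exc = ln$x, w_inh = ln$y, level = ln$level))
  }
  structure(list(w_exc = w_exc, w_inh = w_inh, re_lambda = re,
                 im_lambda = im, rate_E = rate, contours = contours),
            class = "plane_map")
}
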