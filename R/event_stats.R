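#' Inter-network-spike interval statistics
#'
#' Onset-to-onset intervals between successive network spikes, their mean
#' (reported in seconds) and coefficient of variation.  A CV near 0 marks
#' quasi-periodic bursting, a CV near 1 Poisson-like rare events.
#'
#' @param events an `event_list` (or any data frame with `onset_ms`); by
#'   default only events labelled `NS` or `UNLABELED` are used
#' @param labels labels counted as network spikes
#' @return list with `mean_insi` (s), `cv_insi`, `n_events`
#' @export
insi_stats <- function(events, labels = c("NS", "UNLABELED")) {
  ev <- events[events$label %in% labels, , drop = FALSE]
  if (nrow(ev) < 3)
    stop("insi_stats: need at least 3 events")
  iv <- diff(sort(ev$onset_ms)) / 1000
  # population (1/n) standard deviation: the CV of the realised intervals
  sd_pop <- sqrt(mean((iv - mean(iv))^2))
  list(mean_insi = mean(iv), cv_insi = sd_pop / mean(iv),
       n_events = nrow(ev))
}

#' Stationary amplitude law of noise-driven quasi-orbits
#'
#' Near a stable focus close to a Hopf bifurcation (dominant eigenvalue
#' \eqn{\Re\lambda < 0}, \eqn{|\Re\lambda| \ll \Im\lambda}), the radius
#' \eqn{l} of noise-driven excursions is Rayleigh distributed,
#' \deqn{p(l) = \frac{4|\Re\lambda|}{\sigma'^2}\, l\,
#'   \exp\left(-\frac{2|\Re\lambda| l^2}{\sigma'^2}\right),}
#' so the squared radius (and hence the event size, which scales with
#' \eqn{l^2}) is exponential with mean \eqn{\sigma'^2 / (2|\Re\lambda|)};
#' \eqn{\sigma'^2 = \sigma_x^2 + \sigma_y^2} is the effective noise power.
#'
#' @param l amplitude value(s)
#' @param re_lambda real part of the dominant eigenvalue (must be < 0);
#'   units are 1/time, matching `sigma_prime^2` per unit time
#' @param sigma_prime effective noise amplitude (> 0)
#' @return density at `l`
#' @export
quasiorbit_size_pdf <- function(l, re_lambda, sigma_prime) {
  if (re_lambda >= 0)
    stop("quasiorbit_size_pdf: the linearised theory requires re_lambda < 0")
  stopifnot(sigma_prime > 0)
  a <- 2 * abs(re_lambda) / sigma_prime^2
  ifelse(l < 0, 0, 2 * a * l * exp(-a * l^2))
}

#' Simulate the noisy planar linear dynamics
#'
#' Euler-Maruyama integration of the two-dimensional linear system in
#' rotating-frame coordinates, with a single white-noise source loading
#' both components,
#' \eqn{\dot x = \Re\lambda\,x - \Im\lambda\,y + \sigma_x \xi},
#' \eqn{\dot y = \Im\lambda\,x + \Re\lambda\,y + \sigma_y \xi}.
#' Serves as the built-in stochastic oracle for the Rayleigh amplitude law
#' (including the phase-averaging step valid for
#' \eqn{\Im\lambda \gg |\Re\lambda|}).
#'
#' @param re_lambda,im_lambda eigenvalue parts (1/s), `re_lambda < 0`
#' @param sigma_x,sigma_y noise loadings (per sqrt(s))
#' @param dt integration step (s)
#' @param n_samples number of radius samples returned
#' @param spacing time between retained samples (s); choose a few
#'   relaxation times `1/|re_lambda|` for effectively independent draws
#' @param burn initial time discarded (s)
#' @return numeric vector of sampled radii `l`
#' @export
simulate_quasiorbit_sde <- function(re_lambda, im_lambda, sigma_x, sigma_y,
                                    dt = 2.5e-4, n_samples = 1e4,
                                    spacing = 2 / abs(re_lambda),
                                    burn = 10 / abs(re_lambda)) {
  stopifnot(re_lambda < 0, dt > 0, n_samples >= 1)
  stride <- max(1L, as.integer(round(spacing / dt)))
  .sim_planar_sde_cpp(re_lambda, im_lambda, sigma_x, sigma_y, dt,
                      as.integer(n_samples), stride,
                      as.integer(ceiling(burn / dt)))
}

# mixture density: left-truncated exponential + Gaussian truncated at x0
mixture_density <- function(x, p0, tau0, x0, m1, s1, log = FALSE) {
  fe <- ifelse(x >= x0, exp(-(x - x0) / tau0) / tau0, 0)
  zg <- pnorm((x0 - m1) / s1, lower.tail = FALSE)
  fg <- ifelse(x >= x0, dnorm(x, m1, s1) / zg, 0)
  d <- p0 * fe + (1 - p0) * fg
  if (log) log(d) else d
}

mixture_negll <- function(par, x) {
  p0 <- par[1]; tau0 <- par[2]; x0 <- par[3]; m1 <- par[4]; s1 <- par[5]
  d <- mixture_density(x, p0, tau0, x0, m1, s1)
  if (any(d <= 0) || any(!is.finite(d))) return(1e12)
  -sum(log(d))
}

#' Fit the exponential-plus-Gaussian event-size mixture
#'
#' Maximum-likelihood fit of the two-component size law
#' \deqn{p(x) = p_0 \frac{1}{\tau_0} e^{-(x - x_0)/\tau_0}
#'  + (1 - p_0)\, \mathcal{N}(x; m_1, \sigma_1)}
#' (both components truncated below the shift \eqn{x_0}, which models the
#' soft detection threshold on event size), by bounded quasi-Newton
#' optimisation with a multistart.  The exponential component describes
#' quasi-orbits, the Gaussian one network spikes.  The classification
#' threshold is the smallest size in \eqn{(x_0, m_1)} at which the two
#' weighted component densities are equal; if no such crossing below the
#' Gaussian peak exists, no threshold is set (`NA`).
#'
#' @param sizes event sizes (>= 50 values)
#' @param n_starts number of multistart initialisations
#' @return object of class `mixture_fit`: list with `p0`, `tau0`, `x0`,
#'   `m1`, `sigma1`, `threshold` (or `NA`), `negloglik`, `convergence`
#' @export
fit_size_mixture <- function(sizes, n_starts = 8) {
  x <- as.numeric(sizes)
  if (length(x) < 50) stop("fit_size_mixture: need at least 50 event sizes")
  xmin <- min(x); xmax <- max(x)
  lower <- c(1e-4, 1e-3 * sd(x), 0, xmin, 1e-3 * sd(x))
  upper <- c(1 - 1e-4, 10 * (xmax - xmin), xmin, 1.5 * xmax, xmax - xmin)
  q <- quantile(x, c(0.25, 0.5, 0.75, 0.9), names = FALSE)
  starts <- list(
    c(0.7, max(q[1] - xmin, sd(x) / 4), xmin * 0.9, q[4], sd(x) / 2),
    c(0.3, max(q[2] - xmin, sd(x) / 4), xmin * 0.5, q[3], sd(x) / 2),
    c(0.9, sd(x), xmin * 0.9, mean(x) + sd(x), sd(x) / 3),
    c(0.1, sd(x) / 2, 0, mean(x), sd(x)),
    c(1 - 1e-4, mean(x) - xmin, xmin * 0.9, q[4], sd(x) / 2),  # ~pure exponential
    c(1e-4, sd(x), xmin * 0.9, mean(x), sd(x)))                # ~pure Gaussian
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1]] <-
      c(runif(1, 0.05, 0.95), runif(1, 0.1, 2) * sd(x), runif(1, 0, xmin),
        runif(1, q[2], xmax), runif(1, 0.2, 1.5) * sd(x))
  }
  best <- NULL
  for (s0 in starts) {
    s0 <- pmin(pmax(s0, lower), upper)
    o <- tryCatch(
      optim(s0, mixture_negll, x = x, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("fit_size_mixture: no start converged")
  par <- best$par
  fit <- structure(list(p0 = par[1], tau0 = par[2], x0 = par[3],
                        m1 = par[4], sigma1 = par[5],
                        threshold = NA_real_, negloglik = best$value,
                        convergence = best$convergence),
                   class = "mixture_fit")
  fit$threshold <- mixture_threshold(fit)
  fit
}

# smallest root of p0 f_exp = (1-p0) f_gauss in (x0, m1)
mixture_threshold <- function(fit) {
  if (fit$m1 <= fit$x0) return(NA_real_)
  zg <- pnorm((fit$x0 - fit$m1) / fit$sigma1, lower.tail = FALSE)
  g <- function(x) fit$p0 * exp(-(x - fit$x0) / fit$tau0) / fit$tau0 -
    (1 - fit$p0) * dnorm(x, fit$m1, fit$sigma1) / zg
  xs <- seq(fit$x0, fit$m1, length.out = 512)
  gv <- g(xs)
  i <- which(gv[-length(gv)] > 0 & gv[-1] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-8)$root
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: p0 = %.3f, tau0 = %.1f, x0 = %.1f, m1 = %.1f, sigma1 = %.1f\n",
              x$p0, x$tau0, x$x0, x$m1, x$sigma1))
  cat(sprintf("  threshold = %s, -logLik = %.2f\n",
              ifelse(is.na(x$threshold), "none", sprintf("%.1f", x$threshold)),
              x$negloglik))
  invisible(x)
}

#' Label events as network spikes or quasi-orbits
#'
#' Events with size at or above the mixture threshold are labelled `NS`
#' (ties go to `NS`), smaller ones `QUASI_ORBIT`.  When the fit sets no
#' threshold, every event is labelled `NS`.
#'
#' @param events an `event_list`
#' @param fit a [fit_size_mixture()] result
#' @return the event list with updated labels
#' @export
classify_events <- function(events, fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!nrow(events)) return(events)
  events$label <- if (is.na(fit$threshold)) "NS" else
    ifelse(events$size >= fit$threshold, "NS", "QUASI_ORBIT")
  events
}

#' Maximum-likelihood power-law fit of avalanche sizes
#'
#' Continuous-approximation maximum likelihood for the tail exponent,
#' \eqn{\hat\alpha = 1 + n / \sum_i \ln(x_i / x_{min})}, with the lower
#' cutoff chosen by minimising the Kolmogorov-Smirnov distance between the
#' tail data and the fitted law over candidate cutoffs (the standard
#' Clauset-Shalizi-Newman recipe).  The continuous estimator is used even
#' for integer sizes; a discretised variant is available for small-size
#' tails.
#'
#' @param sizes event sizes (>= 100 values)
#' @param xmins candidate cutoffs (default: unique sizes, thinned to at
#'   most `max_candidates`)
#' @param max_candidates cap on the number of candidate cutoffs
#' @param discrete use the discretised estimator
#'   \eqn{\hat\alpha = 1 + n / \sum \ln(x_i / (x_{min} - 1/2))}
#' @return object of class `powerlaw_fit`: list with `alpha`, `xmin`, `ks`,
#'   `n_tail`
#' @export
fit_power_law <- function(sizes, xmins = NULL, max_candidates = 200,
                          discrete = FALSE) {
  x <- as.numeric(sizes[sizes > 0])
  if (length(x) < 100) stop("fit_power_law: need at least 100 sizes")
  if (is.null(xmins)) {
    xmins <- sort(unique(x))
    xmins <- xmins[xmins < quantile(x, 0.95)]
    if (length(xmins) > max_candidates)
      xmins <- unique(quantile(xmins, seq(0, 1, length.out = max_candidates),
                               type = 1, names = FALSE))
  }
  best <- NULL
  for (xm in xmins) {
    tail_x <- x[x >= xm]
    n <- length(tail_x)
    if (n < 10) next
    denom <- if (discrete) sum(log(tail_x / (xm - 0.5)))
             else sum(log(tail_x / xm))
    if (denom <= 0) next
    alpha <- 1 + n / denom
    xs <- sort(tail_x)
    emp <- seq_len(n) / n
    theo <- 1 - (xs / xm)^(1 - alpha)
    ks <- max(pmax(abs(emp - theo), abs(emp - 1 / n - theo)))
    if (is.null(best) || ks < best$ks)
      best <- list(alpha = alpha, xmin = xm, ks = ks, n_tail = n)
  }
  if (is.null(best)) stop("fit_power_law: no admissible cutoff")
  if (best$n_tail < 30)
    warning("fit_power_law: fewer than 30 tail observations; ",
            "the fit is unreliable")
  structure(best, class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("powerlaw_fit: alpha = %.3f, xmin = %g, KS = %.4f (n_tail = %d)\n",
              x$alpha, x$xmin, x$ks, x$n_tail))
  invisible(x)
}
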