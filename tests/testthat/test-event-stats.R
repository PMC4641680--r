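fake_events <- function(onsets_ms, sizes = NULL, dt_bin = 1,
                        label = "UNLABELED") {
  n <- length(onsets_ms)
  if (is.null(sizes)) sizes <- rep(100, n)
  structure(data.frame(onset_bin = as.integer(onsets_ms / dt_bin),
                       offset_bin = as.integer(onsets_ms / dt_bin) + 1L,
                       onset_ms = onsets_ms, duration_ms = dt_bin,
                       size = sizes, peak = 1L, label = label),
            class = c("event_list", "data.frame"), dt_bin = dt_bin)
}

test_that("interval statistics: arithmetic, periodic and Poisson limits", {
  s <- insi_stats(fake_events(c(0, 1000, 3000)))
  expect_equal(s$mean_insi, 1.5)
  expect_equal(s$cv_insi, 0.5 / 1.5, tolerance = 1e-12)

  expect_equal(insi_stats(fake_events(seq(0, 1e5, by = 500)))$cv_insi, 0)

  set.seed(2)
  onsets <- cumsum(rexp(1e4, 1 / 700))
  expect_equal(insi_stats(fake_events(onsets))$cv_insi, 1, tolerance = 0.03)

  expect_error(insi_stats(fake_events(c(0, 1000))), "at least 3")
})

test_that("quasi-orbit amplitude law is a normalised Rayleigh with the stated moment", {
  for (re in c(-1, -2, -5)) {
    for (sp in c(0.5, 1, 2)) {
      nrm <- integrate(quasiorbit_size_pdf, 0, Inf, re_lambda = re,
                       sigma_prime = sp, rel.tol = 1e-10)$value
      expect_equal(nrm, 1, tolerance = 1e-8)
      m2 <- integrate(function(l) l^2 * quasiorbit_size_pdf(l, re, sp),
                      0, Inf, rel.tol = 1e-10)$value
      expect_equal(m2, sp^2 / (2 * abs(re)), tolerance = 1e-7)
    }
  }
  expect_error(quasiorbit_size_pdf(1, 0.5, 1), "re_lambda < 0")
})

test_that("the planar noisy focus reproduces the Rayleigh law (SDE oracle)", {
  set.seed(77)
  # moment scaling across a 3x3 grid: E[l^2] = sigma'^2 / (2 |Re lambda|)
  for (re in c(-1, -2, -5)) {
    for (sp in c(0.5, 1, 2)) {
      l <- simulate_quasiorbit_sde(re, 40, sp / sqrt(2), sp / sqrt(2),
                                   dt = 2.5e-4, n_samples = 4000,
                                   spacing = 2.5 / abs(re))
      m2 <- mean(l^2)
      expected <- sp^2 / (2 * abs(re))
      se <- sd(l^2) / sqrt(length(l))
      expect_lt(abs(m2 - expected), 3 * se + 0.02 * expected)
    }
  }
  # distributional agreement at the 1% level
  l <- simulate_quasiorbit_sde(-2, 40, 1 / sqrt(2), 1 / sqrt(2),
                               dt = 2.5e-4, n_samples = 1e5, spacing = 1)
  # closed-form CDF: P(L <= q) = 1 - exp(-2 |Re lambda| q^2 / sigma'^2)
  ks <- ks.test(l, function(q) 1 - exp(-2 * 2 * q^2 / 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("the size-mixture fit recovers planted parameters and nests its components", {
  x <- make_mixture_sample(5000, p0 = 0.7, tau0 = 200, x0 = 100, m1 = 2000,
                           sigma1 = 300, seed = 10)
  fit <- fit_size_mixture(x)
  expect_equal(fit$p0, 0.7, tolerance = 0.05)
  expect_equal(fit$tau0, 200, tolerance = 200 * 0.1)
  expect_equal(fit$m1, 2000, tolerance = 2000 * 0.02)
  expect_equal(fit$sigma1, 300, tolerance = 300 * 0.15)
  expect_true(fit$threshold > fit$x0 && fit$threshold < fit$m1)

  # pure Gaussian sample: exponential weight collapses
  xg <- make_mixture_sample(2000, p0 = 0, tau0 = 1, x0 = 0, m1 = 1000,
                            sigma1 = 100, seed = 11)
  fg <- fit_size_mixture(xg)
  expect_true(fg$p0 < 0.05 || is.na(fg$threshold) || fg$threshold < min(xg))

  # the mixture optimum is at least as good as either pure component
  nll_pure <- function(x, exponential) {
    if (exponential) {
      x0 <- min(x) * 0.999
      -sum(log(exp(-(x - x0) / mean(x - x0)) / mean(x - x0)))
    } else {
      -sum(log(dnorm(x, mean(x), sd(x)) /
                 pnorm((min(x) * 0.999 - mean(x)) / sd(x),
                       lower.tail = FALSE)))
    }
  }
  expect_lte(fit$negloglik, nll_pure(x, TRUE) + 1e-6)
  expect_lte(fit$negloglik, nll_pure(x, FALSE) + 1e-6)
})

test_that("the equal-probability threshold exists for well-separated components", {
  fit <- structure(list(p0 = 0.5, tau0 = 1, x0 = 0, m1 = 10, sigma1 = 1),
                   class = "mixture_fit")
  thr <- netevents:::mixture_threshold(fit)
  expect_true(is.finite(thr))
  expect_lt(thr, 10)
  expect_gt(thr, 0)
})

test_that("event classification by threshold is deterministic and idempotent", {
  ev <- fake_events(c(0, 10, 20, 30) * 1000, sizes = c(100, 499, 500, 900))
  fit <- structure(list(p0 = 0.5, tau0 = 100, x0 = 0, m1 = 700, sigma1 = 100,
                        threshold = 500), class = "mixture_fit")
  lab <- classify_events(ev, fit)
  expect_equal(lab$label, c("QUASI_ORBIT", "QUASI_ORBIT", "NS", "NS"))
  expect_equal(classify_events(lab, fit)$label, lab$label)
  fit$threshold <- NA_real_
  expect_true(all(classify_events(ev, fit)$label == "NS"))
})

test_that("power-law fitting matches its closed form and is consistent", {
  # closed form on a three-point sample with fixed cutoff
  f <- fit_power_law(rep(c(2, 4, 8), 40), xmins = 2)
  expect_equal(f$alpha, 1 + 3 / (log(2) + log(4)), tolerance = 1e-12)
  expect_equal(f$alpha, 2.443, tolerance = 1e-3)

  # Pareto sample with known exponent
  set.seed(9)
  x <- 1 * runif(1e4)^(-1 / 0.5)   # alpha = 1.5, xmin = 1
  f2 <- fit_power_law(x)
  expect_equal(f2$alpha, 1.5, tolerance = 0.05 / 1.5)

  # exponent invariant under rescaling sizes and cutoffs together
  f3 <- fit_power_law(x * 37)
  expect_equal(f3$alpha, f2$alpha, tolerance = 1e-9)
  expect_equal(f3$xmin, f2$xmin * 37, tolerance = 1e-9)

  expect_error(fit_power_law(1:50), "at least 100")
})
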