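test_that("the fatigue integrator matches its closed forms and a fine-step oracle", {
  # constant drive: steady state nu * tau
  f <- integrate_fatigue(rep(3, 4000), dt = 0.01, tau_star = 0.5)
  expect_equal(f[length(f)], 1.5, tolerance = 1e-6)
  # pure decay from f0 = 1 over one time constant
  f2 <- integrate_fatigue(rep(0, 101), dt = 0.01, tau_star = 1, f0 = 1)
  expect_equal(f2[101], exp(-1), tolerance = 1e-12)
  # brute-force fine-step Euler oracle (its own bias is ~h / 2 tau, so the
  # refinement is chosen to keep it beneath the comparison tolerance)
  set.seed(14)
  rate <- rexp(300, 1 / 3)
  dt <- 0.02
  for (tau in c(0.5, 1, 5)) {
    expect_rel_equal(integrate_fatigue(rate, dt, tau) + 1e-9,
                     fatigue_euler_oracle(rate, dt, tau, refine = 500) + 1e-9,
                     1e-4)
  }
})

test_that("the effective depression timescale equals the linearised resource relaxation", {
  expect_equal(effective_timescale(0.8, 0.2, 0), 0.8)
  expect_equal(effective_timescale(0.8, 0.2, 3), 0.8 / 1.48, tolerance = 1e-12)
  expect_equal(0.8 / 1.48, 0.541, tolerance = 1e-3)
  # identity with tau_STD * <r> at the activity-dependent stationary point
  for (u in c(0.1, 0.2, 0.5)) {
    for (tau in c(0.3, 0.8, 2)) {
      for (nu in c(0.5, 3, 10)) {
        r_bar <- 1 / (1 + u * nu * tau)
        expect_equal(effective_timescale(tau, u, nu), tau * r_bar,
                     tolerance = 1e-12)
      }
    }
  }
  nus <- seq(0, 20, by = 0.5)
  expect_true(all(diff(effective_timescale(0.8, 0.2, nus)) < 0))
})

make_scan_fixture <- function(seed, tau_true = 0.5, n_events = 400,
                              slope = -3) {
  set.seed(seed)
  n <- 5e4
  rate <- rpois(n, 4) + 0.5 * sin(seq_len(n) / 50)
  f <- integrate_fatigue(rate, 0.004, tau_true)
  onsets <- sort(sample(2000:(n - 10), n_events))
  sizes <- slope * f[onsets + 1] + 100
  list(rate = rate, events = data.frame(onset_bin = onsets, size = sizes))
}

test_that("a planted linear fatigue-size relation is recovered at the generating timescale", {
  fx <- make_scan_fixture(1)
  grid <- 10^seq(log10(0.05), log10(10), length.out = 40)
  sc <- correlation_scan(fx$rate, 0.004, fx$events, tau_grid = grid,
                         B = 200, seed = 2)
  expect_equal(nrow(sc$optima), 1)
  expect_lt(min(sc$correlation), -0.999)
  # global minimum within one grid step of the generating timescale
  i_opt <- which.min(abs(grid - sc$optima$tau_star_grid[1]))
  i_true <- which.min(abs(grid - 0.5))
  expect_lte(abs(i_opt - i_true), 1)
  # sub-grid refinement lands even closer
  expect_equal(sc$optima$tau_star_opt[1], 0.5, tolerance = 0.06)

  # invariance under grid refinement: optimum moves by at most one step
  grid2 <- 10^seq(log10(0.05), log10(10), length.out = 80)
  sc2 <- correlation_scan(fx$rate, 0.004, fx$events, tau_grid = grid2,
                          B = 100, seed = 3)
  expect_lt(abs(log(sc2$optima$tau_star_opt[1] / sc$optima$tau_star_opt[1])),
            log(grid[2] / grid[1]) + 1e-9)
})

test_that("two planted fatigue mechanisms produce two significant scan minima", {
  # the drive needs separated fast and slow variance components (as bursty
  # recordings have): Pearson correlation is bilinear, so with a
  # single-timescale drive the two kernel-correlation bumps overlap into
  # one bowl no matter how the sizes are constructed
  set.seed(4)
  n <- 2e5
  dt <- 0.004
  t_s <- (1:n) * dt
  slow <- 4 * (1 + sin(2 * pi * t_s / 40))
  rate <- rpois(n, 0.2 + slow * dt * 2)
  burst_at <- which(runif(n) < dt)            # ~ one fast burst per second
  for (b in burst_at) rate[b:min(b + 9, n)] <- rate[b:min(b + 9, n)] + 30
  f1 <- integrate_fatigue(rate, dt, 0.4)
  f2 <- integrate_fatigue(rate, dt, 20)
  onsets <- sort(sample(20000:(n - 10), 600))
  z <- function(v) (v - mean(v)) / sd(v)
  sizes <- -z(f1[onsets + 1]) - z(f2[onsets + 1]) + rnorm(600, sd = 0.3)
  ev <- data.frame(onset_bin = onsets, size = sizes)
  sc <- correlation_scan(rate, dt, ev,
                         tau_grid = 10^seq(log10(0.05), log10(100),
                                           length.out = 50),
                         B = 300, seed = 5)
  expect_gte(nrow(sc$optima), 2)
  o <- sc$optima[order(sc$optima$correlation), ][1:2, ]
  # two well-separated timescales, one on each side of the planted pair's
  # geometric midpoint (the peaks attract each other, so the recovered
  # ratio understates the planted factor 50)
  expect_gt(max(o$tau_star_opt) / min(o$tau_star_opt), 6)
  expect_lt(min(o$tau_star_opt), 2)
  expect_gt(max(o$tau_star_opt), 4)
})

test_that("independent sizes produce no significant negative peak", {
  hits <- 0
  for (seed in 1:10) {
    fx <- make_scan_fixture(seed + 100)
    set.seed(seed)
    fx$events$size <- sample(fx$events$size)
    sc <- correlation_scan(fx$rate, 0.004, fx$events,
                           tau_grid = 10^seq(log10(0.1), log10(5),
                                             length.out = 15),
                           B = 200, seed = seed)
    if (nrow(sc$optima) > 0) hits <- hits + 1
  }
  expect_lte(hits, 1)
})

test_that("depression parameters are recovered from effective-timescale pairs", {
  nus <- c(1, 2, 3.5, 5, 8, 12)
  taus <- effective_timescale(0.8, 0.2, nus)
  fit <- fit_std_params(nus, taus)
  expect_equal(fit$tau_STD_hat, 0.8, tolerance = 1e-6)
  expect_equal(fit$u_STD_hat, 0.2, tolerance = 1e-6)

  # 10% multiplicative noise on the measured timescales
  set.seed(6)
  ok <- replicate(5, {
    fitn <- fit_std_params(nus, taus * (1 + rnorm(6, sd = 0.1)))
    abs(fitn$tau_STD_hat - 0.8) / 0.8 < 0.2 &&
      abs(fitn$u_STD_hat - 0.2) / 0.2 < 0.6
  })
  expect_gte(sum(ok), 4)

  expect_warning(fit_std_params(c(3, 3.1, 3.2, 3.3),
                                effective_timescale(0.8, 0.2, c(3, 3.1, 3.2, 3.3))),
                 "factor 2")
  expect_error(fit_std_params(c(1, 2), c(0.7, 0.6)), "at least 4")
})

test_that("pre-event precursors correlate with the sign the physics dictates", {
  set.seed(16)
  n <- 2e4
  precursor <- as.numeric(stats::filter(rnorm(n), 0.995,
                                        method = "recursive"))
  onsets <- sort(sample(100:(n - 1), 200))
  sizes <- 5 * precursor[onsets] + rnorm(200, sd = 0.5)
  ev <- data.frame(onset_bin = onsets, size = sizes)
  pc <- precursor_correlation(ev, precursor, alternative = "greater",
                              seed = 1)
  expect_gt(pc$correlation, 0.5)
  expect_lt(pc$p_value, 0.01)
  # shuffled sizes fall inside the null band
  ev$size <- sample(ev$size)
  pc0 <- precursor_correlation(ev, precursor, seed = 2)
  expect_gt(pc0$p_value, 0.05)
})
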