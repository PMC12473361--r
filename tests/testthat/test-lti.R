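test_that("linear simulation honours trivial limits", {
  fs <- 200
  dp <- rnorm(2000)
  expect_equal(simulate_linear(dp, tau = 0.1, gain = 0, fs), rep(0, 2000))
  # constant input: no derivative drive, output stays zero
  expect_equal(simulate_linear(rep(7, 2000), tau = 0.1, gain = 0.05, fs), rep(0, 2000))
  expect_error(simulate_linear(dp, tau = -1, gain = 1, fs), "tau")
})

test_that("step response converges first-order to (G*A/tau)*exp(-t/tau)", {
  tau <- 0.2
  G <- 0.05
  A <- 3
  err_at <- function(fs) {
    n <- round(2 * fs)
    x <- c(0, rep(A, n))                      # step after the first sample
    y <- simulate_linear(x, tau, G, fs)
    t <- (seq_along(x) - 2) / fs              # time since the step
    yref <- ifelse(t >= 0, (G * A / tau) * exp(-t / tau), 0)
    max(abs(y - yref))
  }
  e1 <- err_at(200)
  e2 <- err_at(400)
  expect_lt(e1, 0.05 * (G * A / tau))
  expect_equal(e1 / e2, 2, tolerance = 0.3)   # halving h halves the error
})

test_that("nonlinear feedback model: fixed point, feedback sign, O(eps^2) linearization error", {
  consts <- physio_constants(P0 = 100, Q0 = 12.5, k = 1)
  fs <- 1000
  n <- 5 * fs
  # equilibrium input is an exact fixed point
  st <- simulate_nonlinear(rep(100, n), consts, fs)
  expect_equal(st$r, rep(consts$R0, n), tolerance = 1e-12)
  expect_equal(st$q, rep(consts$Q0, n), tolerance = 1e-12)
  expect_equal(st$q, st$p / st$r)

  # pressure step: flow relaxes toward Q0, resistance rises while Q > Q0
  p_step <- c(rep(100, 100), rep(101, n - 100))
  st2 <- simulate_nonlinear(p_step, consts, fs)
  over <- st2$q > consts$Q0 + 1e-9
  expect_true(any(over))
  expect_true(all(diff(st2$r)[which(over[-1])] > 0))
  expect_lt(abs(st2$q[n] - consts$Q0), abs(st2$q[101] - consts$Q0) * 0.1)

  # linearization error scales ~quadratically in the perturbation size
  lp <- physio_params(consts)
  lin_err <- function(eps) {
    p <- c(rep(100, 100), rep(100 * (1 + eps), n - 100))
    nl <- simulate_nonlinear(p, consts, fs)
    t <- pmax((seq_len(n) - 101) / fs, 0)
    dq_lin <- ifelse(seq_len(n) > 100,
                     (lp$gain * 100 * eps / lp$tau) * exp(-t / lp$tau), 0)
    max(abs(nl$q - (consts$Q0 + dq_lin)))
  }
  ratio <- lin_err(0.02) / lin_err(0.01)
  expect_equal(ratio, 4, tolerance = 0.3)

  expect_error(simulate_nonlinear(c(rep(100, 10), rep(1e-6, 5000)), consts, 10),
               "non-positive|positive")
})

test_that("physiological constants map to (tau, gain) with ratio R0", {
  expect_equal(physio_params(physio_constants(P0 = 1, Q0 = 1, k = 1)),
               list(tau = 1, gain = 1))
  withr::with_seed(5, {
    for (i in 1:10) {
      P0 <- runif(1, 50, 150); Q0 <- runif(1, 1, 20); k <- runif(1, 0.1, 10)
      pc <- physio_constants(P0, Q0, k)
      lp <- physio_params(pc)
      expect_equal(lp$tau / lp$gain, pc$R0, tolerance = 1e-12)  # Eq ratio, floating-exact
      lp2 <- physio_params(physio_constants(P0, Q0, 2 * k))
      expect_equal(lp2$tau, lp$tau / 2)
      expect_equal(lp2$gain, lp$gain / 2)
    }
  })
  expect_error(physio_constants(-1, 1, 1), "positive")
})

test_that("ARX identification is exact on its own generative model", {
  fs <- 200
  withr::with_seed(6, dp <- cumsum(rnorm(5000)) * 0.1 + 80)
  dq <- simulate_linear(dp, tau = 0.1, gain = 0.05, fs)
  fit <- fit_lti(dp, dq, fs, method = "arx")
  expect_equal(fit$tau, 0.1, tolerance = 1e-9)
  expect_equal(fit$gain, 0.05, tolerance = 1e-9)
  expect_equal(fit$alpha, 0.1 / (0.1 + 1 / fs), tolerance = 1e-9)
  expect_true(fit$stable)
  # offset invariance: centering plus intercept absorbs constants
  fit2 <- fit_lti(dp + 55, dq - 3, fs, method = "arx")
  expect_equal(fit2$tau, fit$tau, tolerance = 1e-8)
  expect_equal(fit2$gain, fit$gain, tolerance = 1e-8)
})

test_that("zero output yields a flagged degenerate fit", {
  fs <- 200
  withr::with_seed(7, dp <- rnorm(2000) + 80)
  expect_warning(fit <- fit_lti(dp, rep(0, 2000), fs), "zero variance")
  expect_equal(fit$gain, 0)
  expect_false(fit$stable)
  expect_match(fit$flags, "degenerate")
})

test_that("output-error refinement recovers parameters under measurement noise", {
  sp <- synth_params(tau_true = 0.0696, gain_true = 0.001, seed = 3)
  rec <- gen_recording(sp)
  sig <- detrend_reg(rec$reg[c("time_s", "z")])
  fit <- fit_lti(rec$bp$p, sig$q, sp$fs)
  expect_equal(fit$tau, sp$tau_true, tolerance = 0.005 / 0.0696)
  expect_equal(fit$gain, sp$gain_true, tolerance = 0.05)
  expect_true(fit$stable)
  expect_lt(fit$rmse, 0.1)
  expect_gt(fit$r2, 0.9)
  td <- tidy(fit)
  expect_setequal(td$term, c("tau", "gain", "alpha", "beta"))
})

test_that("goodness-of-fit definitions hold at their fixed points", {
  x <- rnorm(100)
  g <- goodness(x, x)
  expect_equal(g$rmse, 0)
  expect_equal(g$r2, 1)
  g0 <- goodness(x, rep(mean(x), 100))
  expect_equal(g0$r2, 0)
  expect_warning(gc <- goodness(rep(1, 50), rnorm(50)), "zero variance")
  expect_true(is.na(gc$r2))
  expect_error(goodness(1:3, 1:4), "differ")
})

test_that("tau recovery holds across the physiological range", {
  taus <- c(0.05, 0.1, 0.2, 0.4)
  n_seeds <- 8
  rel_err <- purrr::map_dbl(taus, function(tau) {
    est <- purrr::map_dbl(seq_len(n_seeds), function(s) {
      sp <- synth_params(tau_true = tau, seed = 100 + s)
      rec <- gen_recording(sp)
      sig <- detrend_reg(rec$reg[c("time_s", "z")])
      fit_lti(rec$bp$p, sig$q, sp$fs)$tau
    })
    median(abs(est - tau) / tau)
  })
  expect_true(all(rel_err < 0.1))
})
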