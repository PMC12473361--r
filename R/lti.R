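# First-order LTI model of dynamic cerebral autoregulation.
#
# Physiology: flow Q(t) = P(t)/R(t) (venous pressure neglected), with
# resistance adjusted by negative feedback toward a target flow Q0:
#   dR/dt = k * (P/R - Q0)
# Linearizing about the operating point (P0, R0, Q0 = P0/R0) gives the
# first-order model in the perturbations:
#   tau * dDQ/dt + DQ = G * dDP/dt,   tau = R0/(k*Q0),   G = 1/(k*Q0)
# tau is the speed of the regulatory response; G its sensitivity to the rate
# of pressure change (near-zero gain = intact regulation).

#' Simulate the linear autoregulation model
#'
#' Integrates `tau * dDQ/dt + DQ = G * dDP/dt` by backward-Euler
#' discretization: with step `h = 1/fs`,
#' `y[n] = alpha*y[n-1] + beta*(x[n]-x[n-1])` where `alpha = tau/(tau+h)`
#' and `beta = G/(tau+h)`, starting from `y = 0`. Only differences of the
#' input enter, so `dp` may be supplied in absolute or perturbation units.
#'
#' @param dp Pressure input series (mmHg), uniformly sampled at `fs`.
#' @param tau Time constant in seconds (> 0).
#' @param gain Gain in ohm/mmHg.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of flow perturbation `DQ` (ohms), same length as
#'   `dp`.
#' @export
simulate_linear <- function(dp, tau, gain, fs) {
  assert_scalar_pos(tau, "tau")
  assert_scalar_pos(fs, "fs")
  h <- 1 / fs
  alpha <- tau / (tau + h)
  beta <- gain / (tau + h)
  dx <- c(0, diff(dp))
  as.numeric(stats::filter(beta * dx, alpha, method = "recursive"))
}

#' Physiological constants of the feedback model
#'
#' @param P0 Steady-state perfusion pressure (mmHg).
#' @param Q0 Steady-state (target) flow.
#' @param k Regulatory rate constant.
#' @param R0 Steady-state resistance; defaults to `P0/Q0` and must agree
#'   with it.
#' @return A list of class `physio_constants`.
#' @export
physio_constants <- function(P0, Q0, k, R0 = P0 / Q0) {
  for (nm in c("P0", "Q0", "k", "R0")) assert_scalar_pos(get(nm), nm)
  if (abs(R0 - P0 / Q0) > 1e-9 * R0) abort("R0 must equal P0/Q0")
  structure(list(P0 = P0, Q0 = Q0, k = k, R0 = R0), class = "physio_constants")
}

#' Map physiological constants to LTI parameters
#'
#' `tau = R0/(k*Q0)` and `gain = 1/(k*Q0)`; their ratio is exactly `R0`.
#'
#' @param consts A [physio_constants()] object.
#' @return A list with `tau` (seconds) and `gain`.
#' @export
physio_params <- function(consts) {
  list(tau = consts$R0 / (consts$k * consts$Q0),
       gain = 1 / (consts$k * consts$Q0))
}

#' Simulate the nonlinear feedback model
#'
#' Integrates the resistance dynamics `dR/dt = k*(P/R - Q0)` with classical
#' 4th-order Runge-Kutta (pressure linearly interpolated at half steps) and
#' records the flow `Q = P/R`. Used to validate the linearized model: for a
#' pressure perturbation of relative size `eps`, the nonlinear and linear
#' trajectories diverge as `O(eps^2)`.
#'
#' @param p Pressure series (mmHg), uniformly sampled, all positive.
#' @param consts A [physio_constants()] object; integration starts at
#'   `R = R0`.
#' @param fs Sampling rate in Hz.
#' @return A tibble with `time_s`, `p`, `r` (resistance) and `q` (flow).
#' @export
simulate_nonlinear <- function(p, consts, fs) {
  assert_scalar_pos(fs, "fs")
  if (any(p <= 0)) abort("pressure must be positive throughout")
  h <- 1 / fs
  n <- length(p)
  r <- numeric(n)
  r[1] <- consts$R0
  k <- consts$k
  q0 <- consts$Q0
  f <- function(pp, rr) k * (pp / rr - q0)
  for (i in seq_len(n - 1)) {
    p1 <- p[i]
    p2 <- p[i + 1]
    pm <- (p1 + p2) / 2
    k1 <- f(p1, r[i])
    k2 <- f(pm, r[i] + h / 2 * k1)
    k3 <- f(pm, r[i] + h / 2 * k2)
    k4 <- f(p2, r[i] + h * k3)
    r[i + 1] <- r[i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(r[i + 1]) || r[i + 1] <= 0) {
      abort(sprintf("resistance driven non-positive at t = %.3f s (non-physiological input)", i * h))
    }
  }
  tibble(time_s = (seq_len(n) - 1) / fs, p = p, r = r, q = p / r)
}

#' Goodness of fit between measured and predicted series
#'
#' Root mean square error and coefficient of determination
#' `R2 = 1 - SS_res/SS_tot`, with `SS_tot` about the measured mean.
#'
#' @param measured,predicted Equal-length numeric vectors.
#' @return A list with `rmse` and `r2`; `r2` is `NA` (with a warning) when
#'   the measured series has zero variance.
#' @export
goodness <- function(measured, predicted) {
  if (length(measured) != length(predicted)) abort("series lengths differ")
  if (length(measured) < 2) abort("need at least 2 samples")
  res <- measured - predicted
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) {
    warn("measured series has zero variance; R2 undefined")
    return(list(rmse = rmse, r2 = NA_real_))
  }
  list(rmse = rmse, r2 = 1 - sum(res^2) / ss_tot)
}

#' Identify the autoregulation model from pressure and REG
#'
#' Estimates the time constant `tau` and gain `G` of the first-order model
#' from a pressure input and a detrended-REG output. Both series are centered
#' internally, so results are invariant to constant offsets.
#'
#' Two estimators are available:
#' \describe{
#'   \item{`"arx"`}{ordinary least squares on the backward-Euler regression
#'     `y[n] ~ y[n-1] + (x[n]-x[n-1])`. Exact when the output is noise-free,
#'     but measurement noise on `y[n-1]` attenuates the autoregressive
#'     coefficient and biases `tau` low.}
#'   \item{`"oe"` (default)}{output-error refinement: starting from the ARX
#'     estimate, `(tau, G)` are adjusted by Levenberg-Marquardt to minimize
#'     the free-run prediction error. Consistent under additive white
#'     measurement noise on the output, which the ARX form is not.}
#' }
#'
#' Goodness of fit is always computed on the free-run (simulation-mode)
#' prediction — the model driven by the input alone — never one-step-ahead,
#' whose errors would be trivially small. The first `warmup_s` seconds are
#' excluded from the error metrics to wash out the `y[1] = 0` initial
#' condition.
#'
#' @param dp Pressure input (mmHg), uniformly sampled at `fs`.
#' @param dq Measured detrended REG output (ohms), same length.
#' @param fs Sampling rate in Hz.
#' @param method `"oe"` (default) or `"arx"`.
#' @param warmup_s Seconds excluded from RMSE/R2 (default 2).
#' @return An object of class `lti_fit`: list with `tau` (s), `gain`
#'   (ohm/mmHg), discrete coefficients `alpha` and `beta`, `predicted`
#'   (free-run series, ohms, centered scale), `rmse`, `r2`, `stable`
#'   (`alpha` inside (0,1)), `flags`, and the call configuration. Unstable
#'   or degenerate estimates are reported and flagged, never silently
#'   clamped.
#' @export
fit_lti <- function(dp, dq, fs, method = c("oe", "arx"), warmup_s = 2) {
  method <- match.arg(method)
  assert_scalar_pos(fs, "fs")
  n <- length(dq)
  if (length(dp) != n) abort("dp and dq must have equal length")
  if (n < 1000) abort("need at least 1000 samples to identify the model")
  h <- 1 / fs
  x <- dp - mean(dp)
  y <- dq - mean(dq)
  keep <- seq.int(from = max(2L, round(warmup_s * fs) + 1L), to = n)
  flags <- character(0)

  if (var(y) == 0) {
    warn("output has zero variance; gain is 0 and tau is degenerate")
    return(new_lti_fit(tau = NA_real_, gain = 0, alpha = 0, beta = 0,
                       offset = 0, predicted = numeric(n), rmse = 0,
                       r2 = NA_real_, stable = FALSE,
                       flags = "degenerate: zero-variance output",
                       method = method, warmup_s = warmup_s, fs = fs, n = n))
  }

  # ARX(1,1) least squares on the backward-Euler form (intercept absorbs
  # the centering constant)
  dx <- diff(x)
  fit0 <- lm(y[-1] ~ y[-n] + dx)
  alpha <- unname(coef(fit0)[2])
  beta <- unname(coef(fit0)[3])
  tau <- alpha * h / (1 - alpha)
  gain <- beta * h / (1 - alpha)
  if (!(alpha > 0 && alpha < 1)) {
    warn(sprintf("ARX estimate alpha = %.4f outside (0,1); model unstable/degenerate", alpha))
    flags <- c(flags, sprintf("arx alpha %.4f outside (0,1)", alpha))
  }

  offset <- 0
  if (method == "oe") {
    # free-run output-error refinement; log-tau keeps tau positive
    tau0 <- if (alpha > 0 && alpha < 1) tau else 0.1
    gain0 <- if (alpha > 0 && alpha < 1) gain else sd(y) / max(sd(dx), 1e-12) * h
    resid_fn <- function(par) {
      sim <- simulate_linear(x, exp(par[1]), par[2], fs)
      y[keep] - sim[keep] - par[3]
    }
    nls <- minpack.lm::nls.lm(
      par = c(log(tau0), gain0, 0), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 100)
    )
    tau <- exp(nls$par[1])
    gain <- nls$par[2]
    offset <- nls$par[3]
    alpha <- tau / (tau + h)
    beta <- gain / (tau + h)
  }

  predicted <- if (alpha > 0 && alpha < 1) {
    simulate_linear(x, tau, gain, fs) + offset
  } else {
    rep(offset, n)  # no stable free-run exists
  }
  g <- goodness(y[keep], predicted[keep])
  new_lti_fit(tau = tau, gain = gain, alpha = alpha, beta = beta,
              offset = offset, predicted = predicted, rmse = g$rmse,
              r2 = g$r2, stable = alpha > 0 && alpha < 1, flags = flags,
              method = method, warmup_s = warmup_s, fs = fs, n = n)
}

new_lti_fit <- function(tau, gain, alpha, beta, offset, predicted, rmse, r2,
                        stable, flags, method, warmup_s, fs, n) {
  structure(
    list(tau = tau, gain = gain, alpha = alpha, beta = beta, offset = offset,
         predicted = predicted, rmse = rmse, r2 = r2, stable = stable,
         flags = flags, method = method, warmup_s = warmup_s, fs = fs, n = n),
    class = "lti_fit"
  )
}

#' @export
print.lti_fit <- function(x, ...) {
  cat("<lti_fit> first-order autoregulation model\n")
  cat(sprintf("  tau  = %.4g s\n  gain = %.4g ohm/mmHg\n", x$tau, x$gain))
  cat(sprintf("  free-run rmse = %.4g ohm, R2 = %.4f  (%s, n = %d, warm-up %g s)\n",
              x$rmse, x$r2, x$method, x$n, x$warmup_s))
  if (!x$stable) cat("  WARNING: unstable/degenerate estimate\n")
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' @export
tidy.lti_fit <- function(x, ...) {
  tibble(term = c("tau", "gain", "alpha", "beta"),
         estimate = c(x$tau, x$gain, x$alpha, x$beta))
}

#' @export
glance.lti_fit <- function(x, ...) {
  tibble(tau = x$tau, gain = x$gain, rmse = x$rmse, r2 = x$r2,
         stable = x$stable, method = x$method, n = x$n)
}
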