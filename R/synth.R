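# Seeded generator of coupled arterial-pressure / REG recordings with known
# ground truth (tau, G, maneuver timing, recovery duration). Stands in for
# unreleased human recordings: every output carries the truth it was built
# from, so downstream recovery of that truth is the package's validation
# surface.

#' Generator configuration
#'
#' Defaults describe a healthy young adult seated-then-standing recording:
#' mean arterial pressure 76.1 mmHg seated rising by 13.1 mmHg after the
#' stand, pulse pressure 55.8 mmHg (108.7/52.9), heart rate 75 beats/min,
#' baseline head impedance 212.2 ohms, autoregulation time constant
#' 0.0696 s, gain 0.001 ohm/mmHg, and white measurement noise with standard
#' deviation equal to the headband's stated absolute impedance error
#' (0.005 ohms).
#'
#' @param fs Sampling rate, Hz.
#' @param duration Recording length, seconds.
#' @param hr Mean heart rate, beats/min (each beat gets a uniform ±3%
#'   interval jitter).
#' @param map0 Seated mean arterial pressure, mmHg.
#' @param pulse_pressure Systolic minus diastolic pressure, mmHg.
#' @param stand_time Sit-to-stand onset, seconds.
#' @param map_step Settled MAP increase after standing, mmHg.
#' @param transient_drop Depth of the transient MAP dip at the stand, mmHg.
#' @param z0 Baseline head impedance, ohms.
#' @param tau_true,gain_true Autoregulation model parameters coupling REG to
#'   pressure (seconds; ohm/mmHg).
#' @param drift_amp Baseline impedance drift amplitude, ohms (slow sinusoid
#'   plus bounded smoothed random walk).
#' @param noise_sigma White measurement noise SD, ohms.
#' @param reg_pulse_amp REG cycle amplitude for morphology-based scenarios,
#'   ohms.
#' @param perturb_cycles Number of post-onset morphologically perturbed
#'   cycles in recovery scenarios.
#' @param seed Integer seed fixing all randomness end to end.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(fs = 200, duration = 300, hr = 75,
                         map0 = 76.1, pulse_pressure = 55.8,
                         stand_time = 150, map_step = 13.1,
                         transient_drop = 15, z0 = 212.2,
                         tau_true = 0.0696, gain_true = 0.001,
                         drift_amp = 1, noise_sigma = 0.005,
                         reg_pulse_amp = 0.2, perturb_cycles = 9,
                         seed = 1) {
  p <- as.list(environment())
  for (nm in c("fs", "duration", "hr")) assert_scalar_pos(p[[nm]], nm)
  structure(p, class = "synth_params")
}

# Two-bump pulse morphologies (log-normal-shaped main systolic peak plus a
# delayed, smaller dicrotic wave), normalized to [0, 1] over one cycle.
lognorm_bump <- function(phase, mu, s) {
  v <- numeric(length(phase))
  ok <- phase > 0
  v[ok] <- exp(-(log(phase[ok] / mu))^2 / (2 * s^2))
  v
}

# The diastolic arch term sin(pi*phase)^0.5 keeps the waveform elevated
# mid-cycle and descending steeply into the end-diastolic minimum at the
# cycle boundary, as real pulse waveforms do; without it the cycle tail is
# flat and trough localization under measurement noise jitters the detected
# cycle boundaries.
pulse_shape_raw <- function(phase, type) {
  arch <- 0.35 * sin(pi * pmin(pmax(phase, 0), 1))^0.5
  switch(type,
    abp = lognorm_bump(phase, 0.18, 0.45) + 0.40 * lognorm_bump(phase, 0.45, 0.20) + arch,
    reg = lognorm_bump(phase, 0.22, 0.50) + 0.45 * lognorm_bump(phase, 0.52, 0.22) + arch,
    # perturbed morphology: single broad delayed bump, no dicrotic wave
    reg_alt = lognorm_bump(phase, 0.48, 0.65) + arch
  )
}

pulse_shape <- function(phase, type = c("abp", "reg", "reg_alt")) {
  type <- match.arg(type)
  raw <- pulse_shape_raw(phase, type)
  ref <- pulse_shape_raw(shape_grid, type)
  (raw - min(ref)) / (max(ref) - min(ref))
}

shape_grid <- (0:4095) / 4096

shape_mean <- function(type) mean(pulse_shape(shape_grid, type))

# Beat start times with per-beat +/-3% interval jitter, covering [0, horizon]
gen_beat_starts <- function(hr, horizon, jitter = 0.03) {
  ibi0 <- 60 / hr
  n_max <- ceiling(horizon / (ibi0 * (1 - jitter))) + 2
  ibis <- ibi0 * (1 + runif(n_max, -jitter, jitter))
  starts <- c(0, cumsum(ibis))
  starts[seq_len(which(starts > horizon)[1])]
}

# Slow (beat-averaged) pressure trajectory of the sit-to-stand maneuver:
# seated plateau, transient dip normalized to depth `transient_drop`, then
# exponential settling at map0 + map_step.
slow_pressure <- function(t, params) {
  s <- pmax(t - params$stand_time, 0)
  dip_raw <- function(u) exp(-u / 4) - exp(-u / 0.8)
  dip_peak <- dip_raw(log(4 / 0.8) / (1 / 0.8 - 1 / 4))
  on <- t >= params$stand_time
  p <- rep(params$map0, length(t))
  p[on] <- params$map0 +
    params$map_step * (1 - exp(-s[on] / 8)) -
    params$transient_drop * dip_raw(s[on]) / dip_peak
  p
}

#' Generate a pulsatile arterial pressure recording
#'
#' Superimposes a per-beat pressure pulse (two-bump arterial morphology at
#' the configured pulse pressure, with beat-to-beat heart-rate jitter) on the
#' slow sit-to-stand trajectory: seated plateau at `map0`, a transient dip of
#' `transient_drop` at `stand_time`, and exponential settling at
#' `map0 + map_step`. The per-beat time average equals the slow trajectory,
#' so beat-to-beat averaging recovers it.
#'
#' @param params A [synth_params()] configuration.
#' @return A tibble with `time_s`, `p` (mmHg) and the ground-truth slow
#'   component `p_slow`; beat onset times attached as attribute
#'   `beat_starts`.
#' @export
gen_abp <- function(params = synth_params()) {
  withr::local_seed(params$seed)
  n <- round(params$duration * params$fs)
  t <- (seq_len(n) - 1) / params$fs
  starts <- gen_beat_starts(params$hr, params$duration + 2)
  beat <- findInterval(t, starts)
  phase <- (t - starts[beat]) / (starts[beat + 1] - starts[beat])
  pulse <- params$pulse_pressure * (pulse_shape(phase, "abp") - shape_mean("abp"))
  slow <- slow_pressure(t, params)
  out <- tibble(time_s = t, p = slow + pulse, p_slow = slow)
  attr(out, "beat_starts") <- starts
  out
}

#' Generate a REG recording coupled to a pressure recording
#'
#' The pulsatile flow perturbation is produced by driving the first-order
#' autoregulation model with the pressure signal
#' (`DQ = simulate_linear(P - map0, tau_true, gain_true)`), so sample-level
#' system identification on the output is exactly well-specified. Baseline
#' drift (slow sinusoid plus a bounded, smoothed random walk of amplitude
#' `drift_amp`) and white measurement noise are added on top of the constant
#' head impedance `z0`. The clean flow perturbation and drift are retained
#' as ground-truth columns.
#'
#' @param bp Pressure tibble from [gen_abp()] (or compatible).
#' @param params A [synth_params()] configuration.
#' @return A tibble with `time_s`, `z` (ohms) and ground-truth channels
#'   `dq_true` and `drift`.
#' @export
gen_reg_from_abp <- function(bp, params = synth_params()) {
  withr::local_seed(params$seed + 1L)
  n <- nrow(bp)
  t <- bp$time_s
  fs <- params$fs
  dq <- simulate_linear(bp$p - params$map0, params$tau_true, params$gain_true, fs)
  phi <- runif(1, 0, 2 * pi)
  rw <- cumsum(rnorm(n))
  win <- round(5 * fs)
  rw <- as.numeric(stats::filter(rw, rep(1 / win, win), sides = 2))
  ok <- which(!is.na(rw))
  rw[seq_len(ok[1] - 1)] <- rw[ok[1]]            # extend edges, no jumps
  rw[seq.int(ok[length(ok)] + 1, length.out = n - ok[length(ok)])] <- rw[ok[length(ok)]]
  rw <- if (max(abs(rw)) > 0) rw / max(abs(rw)) else rw
  drift <- params$drift_amp * (0.7 * sin(2 * pi * 0.02 * t + phi) + 0.3 * rw)
  noise <- rnorm(n, 0, params$noise_sigma)
  tibble(time_s = t, z = params$z0 + dq + drift + noise, dq_true = dq, drift = drift)
}

#' Generate a full coupled recording
#'
#' @param params A [synth_params()] configuration.
#' @return A list with `bp`, `reg` and `truth` (the generating parameters).
#' @export
gen_recording <- function(params = synth_params()) {
  bp <- gen_abp(params)
  reg <- gen_reg_from_abp(bp, params)
  list(bp = bp, reg = reg,
       truth = list(tau = params$tau_true, gain = params$gain_true,
                    stand_time = params$stand_time, seed = params$seed))
}

#' Generate a recovery-curve scenario with known cycle count
#'
#' Builds a REG recording from cycle morphologies directly: pre-onset cycles
#' use the clean two-bump REG shape; starting at the first cycle after
#' `stand_time`, exactly `perturb_cycles` cycles are blended toward an
#' altered morphology (blend factor chosen deterministically so each
#' perturbed cycle's correlation with the clean shape falls below 0.9, with
#' a 1.3x amplitude fluctuation); subsequent cycles revert to the clean
#' shape. Drift and measurement noise are added as configured.
#'
#' @param params A [synth_params()] configuration (`perturb_cycles`,
#'   `stand_time`, `reg_pulse_amp`, `noise_sigma`, `drift_amp` are the
#'   relevant knobs).
#' @return A list with `reg` (tibble `time_s`, `z`) and `truth` (list with
#'   `onset_time` — the exact start of the first perturbed-slot cycle —
#'   `onset_cycle`, `perturb_cycles`, `lambda`).
#' @export
gen_recovery_scenario <- function(params = synth_params()) {
  withr::local_seed(params$seed + 2L)
  fs <- params$fs
  n <- round(params$duration * fs)
  t <- (seq_len(n) - 1) / fs
  starts <- gen_beat_starts(params$hr, params$duration + 2)
  beat <- findInterval(t, starts)
  phase <- (t - starts[beat]) / (starts[beat + 1] - starts[beat])

  w_clean <- pulse_shape(shape_grid, "reg")
  w_alt <- pulse_shape(shape_grid, "reg_alt")
  lambda <- blend_lambda(w_clean, w_alt, target_r = 0.88)

  onset_cycle <- which(starts >= params$stand_time)[1]
  if (is.na(onset_cycle)) abort("stand_time is beyond the recording")
  perturbed <- beat >= onset_cycle & beat < onset_cycle + params$perturb_cycles

  q <- params$reg_pulse_amp * pulse_shape(phase, "reg")
  if (any(perturbed)) {
    blend <- (1 - lambda) * pulse_shape(phase[perturbed], "reg") +
      lambda * pulse_shape(phase[perturbed], "reg_alt")
    q[perturbed] <- 1.3 * params$reg_pulse_amp * blend
  }
  phi <- runif(1, 0, 2 * pi)
  drift <- params$drift_amp * 0.5 * sin(2 * pi * 0.02 * t + phi)
  z <- params$z0 + q + drift + rnorm(n, 0, params$noise_sigma)
  list(
    reg = tibble(time_s = t, z = z),
    truth = list(onset_time = starts[onset_cycle], onset_cycle = onset_cycle,
                 perturb_cycles = params$perturb_cycles, lambda = lambda)
  )
}

# Smallest blend factor (on a 0.01 grid) pulling the perturbed morphology's
# correlation with the clean shape below target_r.
blend_lambda <- function(w_clean, w_alt, target_r = 0.88) {
  for (lam in seq(0, 1, by = 0.01)) {
    if (cor((1 - lam) * w_clean + lam * w_alt, w_clean) < target_r) return(lam)
  }
  1
}

#' Draw a synthetic cohort of autoregulation parameters
#'
#' Draws per-subject `(tau, gain)` from group-wise normal distributions
#' (`tau` truncated to be positive by redraw), optionally generating a full
#' coupled recording per subject.
#'
#' @param n_per_group Subjects per group (at least 2).
#' @param groups A data frame with columns `group`, `tau_mean`, `tau_sd`,
#'   `gain_mean`, `gain_sd`; defaults to a young and a middle-aged healthy
#'   adult profile.
#' @param seed Integer seed.
#' @param recordings If `TRUE`, attach a list-column of [gen_recording()]
#'   outputs (slow; off by default).
#' @param params Base [synth_params()] used when `recordings = TRUE`.
#' @return A tibble with `group`, `subject`, `tau`, `gain` (and `recording`
#'   when requested).
#' @export
gen_cohort <- function(n_per_group = 30, groups = cohort_profiles(), seed = 1,
                       recordings = FALSE, params = synth_params(seed = seed)) {
  if (n_per_group < 2) abort("n_per_group must be at least 2")
  withr::local_seed(seed)
  out <- purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    tau <- rnorm(n_per_group, groups$tau_mean[g], groups$tau_sd[g])
    while (any(tau <= 0)) {
      tau[tau <= 0] <- rnorm(sum(tau <= 0), groups$tau_mean[g], groups$tau_sd[g])
    }
    tibble(group = groups$group[g], subject = seq_len(n_per_group),
           tau = tau, gain = rnorm(n_per_group, groups$gain_mean[g], groups$gain_sd[g]))
  })
  if (recordings) {
    out$recording <- purrr::map(seq_len(nrow(out)), function(i) {
      p <- params
      p$tau_true <- out$tau[i]
      p$gain_true <- max(out$gain[i], 0)
      p$seed <- seed + i
      gen_recording(p)
    })
  }
  out
}

#' Default cohort group profiles
#'
#' Group means and SDs of the autoregulation parameters for healthy young
#' (18-25 y) and middle-aged (50-60 y) adults.
#'
#' @return A tibble with one row per group.
#' @export
cohort_profiles <- function() {
  tibble(
    group = c("young", "middle_aged"),
    tau_mean = c(0.0696, 0.2006), tau_sd = c(0.005, 0.0045),
    gain_mean = c(2.7355e-9, 0.001), gain_sd = c(2.5114e-9, 8.0986e-5)
  )
}
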