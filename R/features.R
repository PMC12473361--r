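# Per-cycle REG area under the curve and beat-to-beat blood-pressure metrics.

#' Area under one REG cycle
#'
#' Trapezoid-rule area of a single cardiac cycle above its own minimum: with
#' cycle samples `Q_1..Q_N` and `minQ = min(Q)`, each adjacent pair
#' contributes `(Q_i + Q_{i+1})/2 - minQ` in sample units, and the summed
#' area is divided by the sampling rate to convert to ohm-seconds. Because
#' the integrand is referenced to the cycle minimum the result is always
#' non-negative and invariant to adding a constant to the whole cycle.
#'
#' @param q Numeric vector of cycle samples (ohms), at least 2.
#' @param fs Sampling rate in Hz.
#' @return A list with `s_total` (ohm-seconds), `n_points` and `min_q`.
#' @examples
#' cycle_auc(c(0, 1), fs = 1) # one trapezoid: 0.5
#' @export
cycle_auc <- function(q, fs) {
  if (length(q) < 2) abort("a cycle needs at least 2 samples")
  assert_scalar_pos(fs, "fs")
  min_q <- min(q)
  s <- sum((q[-length(q)] + q[-1]) / 2 - min_q)
  list(s_total = s / fs, n_points = length(q), min_q = min_q)
}

#' Per-cycle AUC series
#'
#' Applies [cycle_auc()] to every accepted cycle, yielding the area time
#' series that tracks beat-by-beat cerebral blood volume throughput.
#'
#' @param sig Detrended REG tibble (`time_s`, `q`).
#' @param cycles Cycle table from [detect_cycles()].
#' @param fs Sampling rate in Hz; inferred if `NULL`.
#' @return A tibble with one row per accepted cycle: `cycle`, `cycle_time`
#'   (cycle midpoint, seconds), `s_total` (ohm-seconds), `n_points`, `min_q`.
#' @export
auc_series <- function(sig, cycles, fs = NULL) {
  fs <- signal_fs(sig, fs)
  col <- signal_value_col(sig)
  x <- sig[[col]]
  cyc <- cycles[cycles$accepted, ]
  purrr::map_dfr(seq_len(nrow(cyc)), function(i) {
    a <- cycle_auc(x[cyc$start_idx[i]:(cyc$end_idx[i] - 1L)], fs)
    tibble(cycle = cyc$cycle[i],
           cycle_time = (cyc$start_s[i] + cyc$end_s[i]) / 2,
           s_total = a$s_total, n_points = a$n_points, min_q = a$min_q)
  })
}

#' Beat-to-beat blood pressure metrics
#'
#' Detects systolic peaks in a continuous arterial pressure signal (same
#' pulse segmentation as the REG cycle detector) and summarizes each
#' trough-to-trough beat: systolic (max), diastolic (min), the true
#' time-averaged mean arterial pressure over the beat, and heart rate from
#' the inter-beat interval. Beat averaging removes the cardiac-frequency
#' oscillation and keeps the slow components relevant to autoregulation.
#'
#' @param bp Pressure tibble (`time_s`, `p` in mmHg).
#' @param fs Sampling rate in Hz; inferred if `NULL`.
#' @param ... Passed to the pulse segmenter (see [detect_cycles()] screens).
#' @return A tibble with one row per accepted beat: `beat`, `beat_time`
#'   (systolic peak time), `sbp`, `dbp`, `map`, `beat_mean` (all mmHg) and
#'   `hr` (beats/min).
#' @export
beat_metrics <- function(bp, fs = NULL, ...) {
  fs <- signal_fs(bp, fs)
  col <- signal_value_col(bp)
  p <- bp[[col]]
  seg <- tryCatch(
    segment_pulses(p, fs, width_range = c(0.5, 1.5), amp_range = c(0.5, 2),
                   min_rise_frac = 0.3, prominence_frac = 0.3, step_mult = 5),
    error = function(e) abort("no beats detected in the pressure signal")
  )
  seg <- seg[seg$accepted, ]
  if (nrow(seg) < 3) abort("no beats detected in the pressure signal")
  ibi <- c(diff(bp$time_s[seg$peak_idx]), NA_real_)
  purrr::map_dfr(seq_len(nrow(seg)), function(i) {
    idx <- seg$start_idx[i]:(seg$end_idx[i] - 1L)
    m <- mean(p[idx])
    tibble(beat = seg$cycle[i], beat_time = bp$time_s[seg$peak_idx[i]],
           sbp = max(p[idx]), dbp = min(p[idx]),
           map = m, beat_mean = m,
           hr = 60 / ibi[i])
  })
}

#' Resample beat means onto a uniform grid
#'
#' Linearly interpolates the per-beat mean pressure onto a uniform sampling
#' grid so the beat-averaged pressure can be paired sample-by-sample with the
#' 200 Hz REG stream. No extrapolation beyond the first/last beat.
#'
#' @param beats Beat table from [beat_metrics()].
#' @param fs Target sampling rate in Hz.
#' @return A tibble with `time_s` and `p` (beat-averaged pressure, mmHg),
#'   spanning `[first beat, last beat]`.
#' @export
resample_beats <- function(beats, fs) {
  assert_scalar_pos(fs, "fs")
  if (nrow(beats) < 2) abort("need at least 2 beats to resample")
  t0 <- beats$beat_time[1]
  t1 <- beats$beat_time[nrow(beats)]
  tt <- seq(ceiling(t0 * fs) / fs, t1, by = 1 / fs)
  tibble(time_s = tt,
         p = approx(beats$beat_time, beats$beat_mean, xout = tt, rule = 1)$y)
}
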