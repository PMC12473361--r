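# Raw impedance -> detrended REG signal -> validated cardiac cycles ->
# standardized (time-normalized, ensemble-averaged) waveform template.

# Digital biquad sections of an order-n Butterworth low-pass.
#
# An 8th-order low-pass at 0.5 Hz on 200 Hz data has a normalized cutoff of
# 0.005; in single-polynomial transfer-function form its poles cluster so
# close to z = 1 that filtering diverges in double precision. The filter is
# therefore realized as a cascade of second-order sections, each obtained by
# bilinear transform (with cutoff prewarping) of one conjugate pole pair of
# the analog prototype.
butter_lowpass_sections <- function(order, cutoff_hz, fs) {
  if (order %% 2 != 0) abort("filter order must be even")
  wa <- 2 * fs * tan(pi * cutoff_hz / fs)  # prewarped analog cutoff (rad/s)
  lapply(seq_len(order / 2), function(k) {
    theta <- pi * (2 * k - 1) / (2 * order)
    p <- wa * complex(real = -sin(theta), imaginary = cos(theta))
    bl <- signal::bilinear(Sz = numeric(0), Sp = c(p, Conj(p)), Sg = wa^2, T = 1 / fs)
    list(
      b = Re(bl$gain * c(1, -(bl$zero[1] + bl$zero[2]), bl$zero[1] * bl$zero[2])),
      a = Re(c(1, -(bl$pole[1] + bl$pole[2]), bl$pole[1] * bl$pole[2]))
    )
  })
}

apply_sections <- function(x, sections) {
  for (s in sections) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# Zero-phase (forward-backward) run of the section cascade with odd-reflection
# padding. Subtracting the padded signal's first value before filtering
# removes the DC start-up transient exactly; the reflection pad absorbs the
# remainder (the slowest section decays with time constant ~1/(sin(pi/16)*wc),
# so the default 30 s pad leaves transients below 1e-7 of signal amplitude at
# a 0.5 Hz cutoff). The construction is symmetric under time reversal.
filtfilt_sections <- function(x, sections, fs, pad_s = 30) {
  n <- length(x)
  pad <- min(n - 1, round(pad_s * fs))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  c0 <- xp[1]
  xp <- xp - c0
  yp <- apply_sections(xp, sections)
  yp <- rev(apply_sections(rev(yp), sections))
  yp[(pad + 1):(pad + n)] + c0
}

#' Extract the baseline impedance drift
#'
#' Low-pass filters a raw impedance series with a zero-phase (bidirectional)
#' Butterworth filter to isolate the slow baseline drift, leaving the
#' cardiac-frequency pulse untouched. Bidirectional filtering doubles the
#' attenuation and cancels phase distortion, so pulse timing is preserved.
#'
#' @param raw Signal tibble (`time_s`, `z` in ohms).
#' @param cutoff_hz Low-pass cutoff in Hz (default 0.5, below the slowest
#'   physiological heart rate).
#' @param order Butterworth order (default 8; must be even).
#' @param fs Sampling rate in Hz; inferred from timestamps if `NULL`.
#' @return A tibble with columns `time_s` and `baseline` (ohms).
#' @export
extract_baseline <- function(raw, cutoff_hz = 0.5, order = 8, fs = NULL) {
  fs <- signal_fs(raw, fs)
  assert_scalar_pos(cutoff_hz, "cutoff_hz")
  if (fs <= 2 * cutoff_hz) abort("sampling rate must exceed twice the cutoff frequency")
  col <- signal_value_col(raw)
  x <- raw[[col]]
  if (length(x) <= 6 * order) abort("input too short for the requested filter order")
  sections <- butter_lowpass_sections(order, cutoff_hz, fs)
  tibble(time_s = raw$time_s, baseline = filtfilt_sections(x, sections, fs))
}

#' Detrend a raw impedance series into a REG signal
#'
#' Subtracts the baseline drift (see [extract_baseline()]) from the raw
#' impedance, yielding the pulsatile REG waveform `q`. The decomposition is
#' exact: `q + baseline` reconstructs the input to floating tolerance.
#'
#' @inheritParams extract_baseline
#' @return A tibble with columns `time_s`, `q` (detrended REG, ohms) and
#'   `baseline` (removed drift, ohms).
#' @export
detrend_reg <- function(raw, cutoff_hz = 0.5, order = 8, fs = NULL) {
  base <- extract_baseline(raw, cutoff_hz = cutoff_hz, order = order, fs = fs)
  col <- signal_value_col(raw)
  tibble(time_s = raw$time_s, q = raw[[col]] - base$baseline, baseline = base$baseline)
}

# Fundamental pulse period (samples) from the autocorrelation peak in the
# physiological heart-rate range (30-240 bpm). Secondary waves (dicrotic
# bumps, derivative side lobes) correlate at sub-cycle lags but the global
# autocorrelation maximum sits at the full cycle.
estimate_period <- function(xc, fs) {
  lag_max <- min(length(xc) - 1, round(2 * fs))
  a <- as.numeric(stats::acf(xc, lag.max = lag_max, plot = FALSE,
                             demean = TRUE)$acf)
  lo <- max(2L, round(0.25 * fs))
  if (lo + 1 > lag_max) return(round(0.25 * fs))
  lags <- lo:lag_max
  lags[which.max(a[lags + 1])]
}

# Shared pulse segmentation for REG cycles and blood-pressure beats.
# Returns all trough-to-trough segments around retained peaks, with reject
# reasons. Location-invariant: works on x - median(x).
segment_pulses <- function(x, fs, width_range, amp_range, min_rise_frac,
                           prominence_frac, step_mult) {
  xc <- x - median(x)
  period <- estimate_period(xc, fs)
  min_dist <- max(2L, round(0.55 * period))  # one retained peak per cycle
  pk <- pracma::findpeaks(xc, minpeakdistance = min_dist, zero = "0")
  if (is.null(pk) || nrow(pk) < 2) abort("no pulse peaks found")
  ord <- order(pk[, 2])
  heights <- pk[ord, 1]
  pos <- pk[ord, 2]
  keep <- heights >= prominence_frac * median(heights)
  heights <- heights[keep]
  pos <- pos[keep]
  if (length(pos) < 2) abort("no pulse peaks found")

  med_ibi <- median(diff(pos))
  # troughs between consecutive peaks, plus edge troughs within ~1.5 IBI;
  # localized on a lightly smoothed signal so measurement noise does not
  # jitter the boundary within the diastolic valley
  smooth_w <- max(1L, round(0.02 * fs))
  xs <- as.numeric(stats::filter(xc, rep(1 / smooth_w, smooth_w), sides = 2))
  xs[is.na(xs)] <- xc[is.na(xs)]
  troughs <- integer(length(pos) + 1)
  for (i in seq_len(length(pos) - 1)) {
    seg <- pos[i]:pos[i + 1]
    troughs[i + 1] <- seg[which.min(xs[seg])]
  }
  lo <- max(1L, pos[1] - round(1.5 * med_ibi))
  seg <- lo:pos[1]
  troughs[1] <- seg[which.min(xs[seg])]
  hi <- min(length(xc), pos[length(pos)] + round(1.5 * med_ibi))
  seg <- pos[length(pos)]:hi
  troughs[length(pos) + 1] <- seg[which.min(xs[seg])]

  start_idx <- troughs[-length(troughs)]
  end_idx <- troughs[-1]
  peak_idx <- pos
  dur <- (end_idx - start_idx) / fs
  amp <- vapply(seq_along(pos), function(i) {
    xc[peak_idx[i]] - min(xc[start_idx[i]:end_idx[i]])
  }, numeric(1))
  # rising-segment screen: require a sustained positive-slope upstroke
  rise_len <- peak_idx - start_idx
  med_rise <- median(rise_len)
  rise_ok <- vapply(seq_along(pos), function(i) {
    if (rise_len[i] < 1) return(FALSE)
    up <- diff(xc[start_idx[i]:peak_idx[i]])
    sum(up > 0) >= min_rise_frac * med_rise
  }, logical(1))
  # step/spike artifact screen: sample-to-sample jumps far beyond the
  # signal's own slew distribution flag the enclosing cycle
  adx <- abs(diff(xc))
  step_thr <- step_mult * quantile(adx, 0.99, names = FALSE)
  step_ok <- vapply(seq_along(pos), function(i) {
    max(adx[start_idx[i]:(end_idx[i] - 1)]) <= step_thr
  }, logical(1))

  med_dur <- median(dur)
  med_amp <- median(amp)
  reason <- rep(NA_character_, length(pos))
  reason[!(dur >= width_range[1] * med_dur & dur <= width_range[2] * med_dur)] <- "width"
  reason[!(amp >= amp_range[1] * med_amp & amp <= amp_range[2] * med_amp)] <- "amplitude"
  reason[!rise_ok] <- "rise"
  reason[!step_ok] <- "step"

  tibble(
    cycle = seq_along(pos),
    start_idx = start_idx, peak_idx = peak_idx, end_idx = end_idx,
    duration_s = dur, amplitude = amp,
    accepted = is.na(reason), reject_reason = reason
  )
}

#' Detect and validate cardiac cycles in a REG signal
#'
#' Locates systolic peaks (S points) as local maxima with a sustained rising
#' upstroke, segments the signal into trough-to-trough cycles each containing
#' one S point, and screens cycles with width and amplitude thresholds
#' relative to the running medians. Spike and step artifacts are excluded by
#' the amplitude rule and a slew-rate rule. Indices are 1-based with
#' half-open `[start_idx, end_idx)` extent.
#'
#' @param sig Detrended REG tibble from [detrend_reg()] (`time_s`, `q`).
#' @param width_range,amp_range Acceptance bands as multiples of the median
#'   cycle duration / amplitude.
#' @param min_rise_frac Minimum fraction of the median rise time over which
#'   the pre-peak upstroke must have positive slope.
#' @param prominence_frac Peak retention threshold as a fraction of the
#'   median peak height.
#' @param step_mult Slew-rate artifact multiplier: a jump exceeding
#'   `step_mult` times the 99th percentile of `|diff(q)|` rejects the cycle.
#' @param fs Sampling rate in Hz; inferred if `NULL`.
#' @return A tibble of cycles with indices, times, `duration_s`, `amplitude`,
#'   `accepted` and `reject_reason` columns.
#' @export
detect_cycles <- function(sig, width_range = c(0.5, 1.5), amp_range = c(0.5, 2),
                          min_rise_frac = 0.3, prominence_frac = 0.3,
                          step_mult = 5, fs = NULL) {
  fs <- signal_fs(sig, fs)
  col <- signal_value_col(sig)
  cyc <- segment_pulses(sig[[col]], fs, width_range, amp_range,
                        min_rise_frac, prominence_frac, step_mult)
  cyc$start_s <- sig$time_s[cyc$start_idx]
  cyc$peak_s <- sig$time_s[cyc$peak_idx]
  cyc$end_s <- sig$time_s[cyc$end_idx]
  cyc
}

#' Time-normalize cycles onto a common phase grid
#'
#' Resamples each accepted cycle to exactly `M` points on a uniform phase
#' grid `[0, 1)` by cubic-spline interpolation, so cycles of different
#' duration become comparable point by point. By default `M` is the mean
#' accepted cycle duration times the sampling rate, i.e. the phase grid of
#' the mean-duration cycle.
#'
#' @param cycles Cycle table from [detect_cycles()].
#' @param sig The REG signal the cycles index into.
#' @param M Output length per cycle; default `round(mean duration * fs)`.
#' @param fs Sampling rate in Hz; inferred if `NULL`.
#' @return A long tibble with columns `cycle`, `phase` and `q`; cycles with
#'   fewer than 4 samples (below the cubic-spline minimum) are skipped with a
#'   message. The mean accepted cycle duration is attached as attribute
#'   `mean_period`.
#' @export
normalize_cycles <- function(cycles, sig, M = NULL, fs = NULL) {
  fs <- signal_fs(sig, fs)
  col <- signal_value_col(sig)
  x <- sig[[col]]
  cyc <- cycles[cycles$accepted, ]
  if (nrow(cyc) == 0) abort("no accepted cycles to normalize")
  mean_period <- mean(cyc$duration_s)
  if (is.null(M)) M <- round(mean_period * fs)
  M <- as.integer(M)
  if (M < 4) abort("M must be at least 4")
  phase_out <- (seq_len(M) - 1) / M
  out <- purrr::map_dfr(seq_len(nrow(cyc)), function(i) {
    idx <- cyc$start_idx[i]:(cyc$end_idx[i] - 1L)
    L <- length(idx)
    if (L < 4) {
      inform(sprintf("skipping degenerate cycle %d (%d samples < 4)", cyc$cycle[i], L))
      return(NULL)
    }
    y <- spline(x = (seq_len(L) - 1) / L, y = x[idx], xout = phase_out)$y
    tibble(cycle = cyc$cycle[i], phase = phase_out, q = y)
  })
  if (nrow(out) == 0) abort("all cycles degenerate; nothing to normalize")
  attr(out, "mean_period") <- mean_period
  out
}

#' Build the standardized REG waveform template
#'
#' Superimposes time-normalized cycles and averages them pointwise, yielding
#' the standardized single-cycle REG waveform used as the reference for the
#' recovery-curve statistic. Averaging over `n` cycles suppresses
#' uncorrelated noise by `1/sqrt(n)` while preserving the shared morphology
#' (primary systolic peak and dicrotic wave).
#'
#' @param normalized Long tibble from [normalize_cycles()].
#' @return An object of class `reg_template`: list with `w` (mean waveform,
#'   ohms), `phase`, `M`, `n_cycles` and `mean_period` (seconds).
#' @export
build_template <- function(normalized) {
  if (is.null(normalized) || nrow(normalized) == 0) abort("no cycles supplied")
  n_cycles <- length(unique(normalized$cycle))
  if (n_cycles < 2) abort("need at least 2 cycles to build a template")
  avg <- normalized |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(w = mean(.data$q), .groups = "drop") |>
    dplyr::arrange(.data$phase)
  structure(
    list(w = avg$w, phase = avg$phase, M = nrow(avg), n_cycles = n_cycles,
         mean_period = attr(normalized, "mean_period")),
    class = "reg_template"
  )
}

#' @export
print.reg_template <- function(x, ...) {
  cat(sprintf("<reg_template> %d points, averaged over %d cycles, mean period %.3f s\n",
              x$M, x$n_cycles, x$mean_period %||% NA_real_))
  invisible(x)
}

#' @export
tidy.reg_template <- function(x, ...) {
  tibble(phase = x$phase, w = x$w)
}

#' Standardized-waveform pipeline helper
#'
#' Convenience wrapper: detect cycles in a baseline window, normalize them
#' and build the template in one call.
#'
#' @param sig Detrended REG tibble.
#' @param baseline_s Use only the first `baseline_s` seconds (default 60);
#'   `Inf` uses the whole signal.
#' @param ... Passed to [detect_cycles()].
#' @return A `reg_template`.
#' @export
standardize_waveform <- function(sig, baseline_s = 60, ...) {
  win <- sig[sig$time_s < sig$time_s[1] + baseline_s, ]
  cycles <- detect_cycles(win, ...)
  build_template(normalize_cycles(cycles, win))
}
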