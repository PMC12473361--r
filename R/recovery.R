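# Recovery-curve statistic: per-cycle correlation of incoming REG cycles
# against the standardized waveform template, and detection of how many
# cycles cerebral blood flow needs to return to steady state after a
# maneuver.

#' Compute the recovery curve
#'
#' Each cycle is time-normalized to the template length and correlated
#' (Pearson) with the standardized waveform. A correlation of 1 means the
#' cycle has the pre-maneuver equilibrium morphology; departures below 1
#' track morphological disturbance. Pearson correlation makes the statistic
#' invariant to per-cycle amplitude scaling and offset.
#'
#' Detected cycle boundaries carry a sample or two of localization jitter
#' (the diastolic valley is shallow relative to measurement noise), which
#' would shift the time-normalized cycle against the template and depress
#' the correlation of a morphologically intact cycle. The time-domain
#' correlation is therefore evaluated over a small window of candidate
#' boundary shifts (`max_shift` samples) and the value at the
#' highest-magnitude alignment is reported, keeping the statistic a
#' per-cycle Pearson correlation while making it insensitive to boundary
#' jitter.
#'
#' @param sig Detrended REG tibble (`time_s`, `q`).
#' @param cycles Cycle table from [detect_cycles()].
#' @param template A `reg_template` built from a pre-maneuver baseline
#'   window (see [standardize_waveform()]).
#' @param fs Sampling rate in Hz; inferred if `NULL`.
#' @param max_shift Boundary-alignment search half-width in samples;
#'   default 1.5% of the template length.
#' @return A tibble of class `recovery_curve` with one row per accepted,
#'   non-degenerate cycle: `cycle`, `cycle_time` (cycle midpoint, s), `r`.
#'   Zero-variance cycles (undefined correlation) are excluded with a
#'   message.
#' @export
recovery_curve <- function(sig, cycles, template, fs = NULL, max_shift = NULL) {
  fs <- signal_fs(sig, fs)
  if (is.null(max_shift)) max_shift <- round(0.015 * template$M)
  col <- signal_value_col(sig)
  x <- sig[[col]]
  cyc <- cycles[cycles$accepted, ]
  if (nrow(cyc) == 0) abort("no accepted cycles")
  M <- template$M
  phase_out <- (seq_len(M) - 1) / M
  n <- length(x)
  r_cycle <- vapply(seq_len(nrow(cyc)), function(i) {
    best <- NA_real_
    for (delta in -max_shift:max_shift) {
      i0 <- cyc$start_idx[i] + delta
      i1 <- cyc$end_idx[i] + delta
      if (i0 < 1 || i1 > n + 1) next
      idx <- i0:(i1 - 1L)
      L <- length(idx)
      if (L < 4) next
      y <- spline(x = (seq_len(L) - 1) / L, y = x[idx], xout = phase_out)$y
      if (sd(y) == 0) next
      rr <- cor(y, template$w)
      if (is.na(best) || abs(rr) > abs(best)) best <- rr
    }
    best
  }, numeric(1))
  out <- tibble(cycle = cyc$cycle,
                cycle_time = (cyc$start_s + cyc$end_s) / 2,
                r = r_cycle)
  n_bad <- sum(is.na(out$r))
  if (n_bad > 0) {
    inform(sprintf("excluding %d zero-variance cycle(s) with undefined correlation", n_bad))
    out <- out[!is.na(out$r), ]
  }
  class(out) <- c("recovery_curve", class(out))
  out
}

#' Detect recovery from the recovery curve
#'
#' Starting at the maneuver onset, finds the first cycle from which the
#' correlation stays at or above `theta` for `m` consecutive cycles; the
#' number of cycles between onset and that point is the cycles-to-recovery
#' count. The persistence requirement `m > 1` prevents a single
#' coincidentally template-like cycle from being declared recovery.
#'
#' @param curve A `recovery_curve` tibble.
#' @param onset_time Maneuver onset in seconds (an explicit event marker;
#'   within the curve's time range).
#' @param theta Correlation threshold for "returned to equilibrium"
#'   (default 0.98).
#' @param m Number of consecutive cycles required at or above `theta`
#'   (default 3).
#' @return An object of class `recovery_result`: list with `onset_cycle`,
#'   `recovery_cycle`, `n_cycles_to_recover`, `recovery_time` (seconds from
#'   onset to the recovery cycle), `stabilized`, and the `theta`/`m` used.
#'   When no qualifying run exists `stabilized` is `FALSE` and the counts
#'   are `NA` (a valid outcome, not an error).
#' @export
detect_recovery <- function(curve, onset_time, theta = 0.98, m = 3) {
  if (onset_time < min(curve$cycle_time) || onset_time > max(curve$cycle_time)) {
    abort("onset_time is outside the recovery curve's time range")
  }
  post <- which(curve$cycle_time >= onset_time)
  onset_pos <- post[1]
  r <- curve$r
  n <- length(r)
  rec_pos <- NA_integer_
  for (i in onset_pos:n) {
    if (i + m - 1 > n) break
    if (all(r[i:(i + m - 1)] >= theta)) {
      rec_pos <- i
      break
    }
  }
  stabilized <- !is.na(rec_pos)
  structure(
    list(
      onset_cycle = curve$cycle[onset_pos],
      recovery_cycle = if (stabilized) curve$cycle[rec_pos] else NA_integer_,
      n_cycles_to_recover = if (stabilized) rec_pos - onset_pos else NA_integer_,
      recovery_time = if (stabilized) curve$cycle_time[rec_pos] - onset_time else NA_real_,
      stabilized = stabilized, onset_time = onset_time, theta = theta, m = m
    ),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("<recovery_result>\n")
  if (x$stabilized) {
    cat(sprintf("  recovered after %d cycle(s) (%.2f s); onset cycle %d, recovery cycle %d\n",
                x$n_cycles_to_recover, x$recovery_time, x$onset_cycle, x$recovery_cycle))
  } else {
    cat("  not stabilized: no run of", x$m, "cycles with r >=", x$theta, "after onset\n")
  }
  cat(sprintf("  theta = %.3f, m = %d\n", x$theta, x$m))
  invisible(x)
}

#' @export
tidy.recovery_result <- function(x, ...) {
  tibble(
    onset_cycle = x$onset_cycle, recovery_cycle = x$recovery_cycle,
    n_cycles_to_recover = x$n_cycles_to_recover,
    recovery_time = x$recovery_time, stabilized = x$stabilized
  )
}

#' @export
glance.recovery_result <- function(x, ...) {
  tibble(n_cycles_to_recover = x$n_cycles_to_recover,
         stabilized = x$stabilized, theta = x$theta, m = x$m)
}
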