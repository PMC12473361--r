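# Fixtures built in code; no stored data.

# Deterministic REG-like pulse train: n_cycles cycles of exact period
# 60/hr seconds, unit shape sin(pi*phase)^1.5 (sharp trough, single peak),
# scaled per cycle by `amps`.
pulse_train <- function(n_cycles = 60, hr = 75, fs = 200, amps = 1) {
  period <- 60 / hr
  spc <- round(period * fs)
  amps <- rep_len(amps, n_cycles)
  q <- unlist(lapply(amps, function(a) {
    ph <- (seq_len(spc) - 1) / spc
    a * sin(pi * ph)^1.5
  }))
  tibble::tibble(time_s = (seq_along(q) - 1) / fs, q = q)
}

# Independent bitwise CRC-16 (non-reflected, xorout 0); oracle for the
# package's table-driven implementation.
crc16_oracle <- function(bytes, poly = 0x1021, init = 0xFFFF) {
  crc <- as.integer(init)
  for (b in as.integer(bytes)) {
    crc <- bitwXor(crc, bitwShiftL(b, 8))
    for (i in 1:8) {
      crc <- if (bitwAnd(crc, 0x8000L) != 0L) {
        bitwAnd(bitwXor(bitwShiftL(crc, 1L), as.integer(poly)), 0xFFFFL)
      } else {
        bitwAnd(bitwShiftL(crc, 1L), 0xFFFFL)
      }
    }
  }
  crc
}

raw_to_hex <- function(r, per_line = 16) {
  hex <- sprintf("%02x", as.integer(r))
  paste(vapply(split(hex, ceiling(seq_along(hex) / per_line)),
               paste, character(1), collapse = " "),
        collapse = "\n")
}

# Frequency-domain oracle for the zero-phase 8th-order Butterworth low-pass:
# multiply the spectrum by the squared magnitude response 1/(1+(f/fc)^(2*order)).
freq_domain_lowpass <- function(x, fs, cutoff_hz, order = 8) {
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  h <- 1 / (1 + (abs(f) / cutoff_hz)^(2 * order))
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

# Hand-built cycles table for bypassing detection in math-level tests.
manual_cycles <- function(starts, ends, peaks, fs) {
  tibble::tibble(
    cycle = seq_along(starts),
    start_idx = starts, peak_idx = peaks, end_idx = ends,
    duration_s = (ends - starts) / fs,
    amplitude = NA_real_, accepted = TRUE, reject_reason = NA_character_,
    start_s = (starts - 1) / fs, peak_s = (peaks - 1) / fs, end_s = (ends - 1) / fs
  )
}
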