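# Tabular signal I/O and timestamp alignment of the impedance and pressure
# streams.

#' Write / read a signal table
#'
#' Signal tables are plain CSV with header `time_s,value`, one row per sample;
#' the same dialect carries REG (ohms) and blood pressure (mmHg). Values are
#' written with full double precision so a write/read round trip is bit-stable.
#'
#' @param x A signal tibble (`time_s` plus one value column).
#' @param path File path.
#' @return `write_signal_csv()` returns `x` invisibly; `read_signal_csv()`
#'   returns a tibble with columns `time_s` and `value_col`.
#' @export
write_signal_csv <- function(x, path) {
  col <- signal_value_col(x)
  # 17 significant digits: lossless double -> text -> double round trip
  lines <- c("time_s,value",
             sprintf("%.17g,%.17g", x$time_s, x[[col]]))
  writeLines(lines, path)
  invisible(x)
}

#' @rdname write_signal_csv
#' @param value_col Name to give the value column on read (e.g. `"z"` for
#'   impedance, `"p"` for pressure).
#' @export
read_signal_csv <- function(path, value_col = "value") {
  # base strtod parsing is correctly rounded, so 17-digit text round-trips
  # to the identical double
  d <- utils::read.csv(path, colClasses = c("numeric", "numeric"))
  out <- tibble(time_s = d$time_s)
  out[[value_col]] <- d$value
  out
}

#' Align impedance and pressure streams by timestamp
#'
#' Crops both series to their common time interval and pairs samples by
#' nearest timestamp, preserving each stream's own clock. No extrapolation is
#' performed: output time ranges are subsets of the inputs, and for streams at
#' the same nominal rate the residual pairing offset is at most half a sample
#' period.
#'
#' @param reg Impedance signal tibble (`time_s`, `z`).
#' @param bp Pressure signal tibble (`time_s`, `p`).
#' @return A list with elements `reg` and `bp`, cropped and row-paired (equal
#'   row counts).
#' @export
align_series <- function(reg, bp) {
  t0 <- max(min(reg$time_s), min(bp$time_s))
  t1 <- min(max(reg$time_s), max(bp$time_s))
  if (t0 > t1) abort("series do not overlap in time; cannot align")
  reg <- reg[reg$time_s >= t0 & reg$time_s <= t1, ]
  if (nrow(reg) == 0) abort("series do not overlap in time; cannot align")
  # nearest-timestamp pairing of bp rows onto the cropped reg clock; pairing
  # searches the full bp series so edge samples still find their closest
  # partner (reg times lie inside bp's range, so this never extrapolates)
  idx <- findInterval(reg$time_s, bp$time_s)
  idx_lo <- pmax(idx, 1L)
  idx_hi <- pmin(idx + 1L, nrow(bp))
  use_hi <- abs(bp$time_s[idx_hi] - reg$time_s) < abs(bp$time_s[idx_lo] - reg$time_s)
  pair <- ifelse(use_hi, idx_hi, idx_lo)
  list(reg = reg, bp = bp[pair, ])
}
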