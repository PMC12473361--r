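# Internal helpers shared across modules.

# Sampling rate of a regular signal tibble. Accepts an explicit override,
# otherwise infers from the median timestamp spacing and checks regularity.
signal_fs <- function(x, fs = NULL, tol_ppm = 1) {
  t <- x$time_s
  if (length(t) < 2) abort("need at least 2 samples to infer a sampling rate")
  dt <- diff(t)
  if (any(dt <= 0)) abort("timestamps must be strictly increasing")
  h <- median(dt)
  if (is.null(fs)) fs <- 1 / h
  # spacing must be uniform to within tol_ppm parts per million
  if (max(abs(dt - 1 / fs)) > (1 / fs) * tol_ppm * 1e-6 + 1e-12) {
    abort("signal is not uniformly sampled at the stated rate")
  }
  fs
}

# Value column of a two-column signal tibble (time_s plus one of z/p/q/value).
signal_value_col <- function(x) {
  cand <- intersect(c("z", "p", "q", "value"), names(x))
  if (length(cand) == 0) abort("no signal value column found (expected z, p, q or value)")
  cand[[1]]
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}
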