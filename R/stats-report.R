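# Group-level statistics and the two-level assessment report.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with the contract checks used
#' throughout the package (3 <= n <= 5000, non-degenerate sample).
#'
#' @param x Numeric sample.
#' @return A list with `W` and `p`.
#' @export
normality_test <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) abort("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(x) == 0) abort("sample has zero variance; normality test undefined")
  s <- shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Two-group comparison of an autoregulation parameter
#'
#' Independent two-sample t-test (equal-variance by default, Welch by flag)
#' with per-group Shapiro-Wilk normality checks attached. Symmetric up to
#' the sign of `t` under group exchange, and invariant under common affine
#' rescaling of both groups.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param var_equal Pooled-variance t-test if `TRUE` (default); Welch
#'   otherwise.
#' @return An object of class `group_comparison`: a one-row tibble with
#'   per-group `n`, `mean`, `sd`, `normality_p`, plus `t_statistic`, `df`
#'   and `p_value`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0) abort("both groups are degenerate (zero variance)")
  tt <- t.test(a, b, var.equal = var_equal)
  norm_p <- function(x) {
    if (length(x) >= 3 && length(x) <= 5000 && sd(x) > 0) normality_test(x)$p else NA_real_
  }
  out <- tibble(
    n_a = length(a), mean_a = mean(a), sd_a = sd(a), normality_p_a = norm_p(a),
    n_b = length(b), mean_b = mean(b), sd_b = sd(b), normality_p_b = norm_p(b),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, var_equal = var_equal
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(group = c("a", "b"),
         n = c(x$n_a, x$n_b), mean = c(x$mean_a, x$mean_b),
         sd = c(x$sd_a, x$sd_b),
         normality_p = c(x$normality_p_a, x$normality_p_b))
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
         var_equal = x$var_equal)
}

#' Two-level autoregulation assessment report
#'
#' Combines the temporal level (cycles to recovery from the recovery curve)
#' and the systems level (time constant and gain of the LTI model, with
#' free-run fit diagnostics) into one structured, machine-readable report.
#' The report is descriptive: no normative "normal/abnormal" thresholds are
#' defined for either level, and it says so explicitly.
#'
#' @param recovery A `recovery_result` from [detect_recovery()].
#' @param fit An `lti_fit` from [fit_lti()].
#' @param config Optional named list echoed into the report (seeds, modes,
#'   thresholds used upstream).
#' @return An object of class `assessment_report`.
#' @export
grade_assessment <- function(recovery, fit, config = list()) {
  flags <- character(0)
  if (!recovery$stabilized) flags <- c(flags, "recovery curve did not stabilize")
  if (!fit$stable) flags <- c(flags, "LTI estimate unstable/degenerate")
  flags <- c(flags, fit$flags)
  structure(
    list(
      temporal = list(
        n_cycles_to_recover = recovery$n_cycles_to_recover,
        recovery_time_s = recovery$recovery_time,
        stabilized = recovery$stabilized,
        theta = recovery$theta, m = recovery$m
      ),
      systems = list(
        tau_s = fit$tau, gain_ohm_per_mmhg = fit$gain,
        rmse_ohm = fit$rmse, r2 = fit$r2,
        method = fit$method, stable = fit$stable
      ),
      flags = flags,
      caveat = "descriptive report; no normative thresholds defined",
      config = config
    ),
    class = "assessment_report"
  )
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("<assessment_report>\n")
  cat("  temporal level:\n")
  if (x$temporal$stabilized) {
    cat(sprintf("    cycles to recovery: %d (%.2f s)\n",
                x$temporal$n_cycles_to_recover, x$temporal$recovery_time_s))
  } else {
    cat("    recovery not detected (did not stabilize)\n")
  }
  cat("  systems level:\n")
  cat(sprintf("    tau = %.4g s, gain = %.4g ohm/mmHg (free-run rmse %.4g, R2 %.4f)\n",
              x$systems$tau_s, x$systems$gain_ohm_per_mmhg,
              x$systems$rmse_ohm, x$systems$r2))
  for (f in x$flags) cat("  flag:", f, "\n")
  cat(" ", x$caveat, "\n")
  invisible(x)
}

#' @export
glance.assessment_report <- function(x, ...) {
  tibble(
    n_cycles_to_recover = x$temporal$n_cycles_to_recover,
    stabilized = x$temporal$stabilized,
    tau = x$systems$tau_s, gain = x$systems$gain_ohm_per_mmhg,
    rmse = x$systems$rmse_ohm, r2 = x$systems$r2,
    n_flags = length(x$flags)
  )
}
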