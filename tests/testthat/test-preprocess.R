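fs <- 200

test_that("baseline extraction has unit DC gain and strong stopband rejection", {
  t <- (0:23999) / fs
  const <- tibble::tibble(time_s = t, z = rep(212.2, length(t)))
  expect_equal(extract_baseline(const)$baseline, rep(212.2, length(t)), tolerance = 1e-12)

  # pure 1.2 Hz pulse at amplitude 1: squared 8th-order magnitude at 2.4x
  # cutoff leaves < 1e-4 (steady state, i.e. away from the record edges
  # where any finite-record zero-phase filter carries boundary error)
  pulse <- tibble::tibble(time_s = t, z = sin(2 * pi * 1.2 * t))
  interior <- t >= 8 & t <= max(t) - 8
  expect_lt(max(abs(extract_baseline(pulse)$baseline[interior])), 1e-4)

  expect_error(extract_baseline(const[1:20, ]), "short")
  expect_error(extract_baseline(const, cutoff_hz = 150), "cutoff")
})

test_that("baseline recovers slow drift under a pulse, matching a frequency-domain oracle", {
  t <- (0:23999) / fs
  drift <- 2 * sin(2 * pi * 0.05 * t)
  x <- drift + 0.2 * sin(2 * pi * 1.2 * t)
  raw <- tibble::tibble(time_s = t, z = x)
  base <- extract_baseline(raw)$baseline
  expect_lt(max(abs(base - drift)), 0.01 * 2)        # < 1% of drift amplitude
  oracle <- freq_domain_lowpass(x, fs, 0.5, 8)
  inner <- 2000:22000                                 # oracle is circular; compare interior
  expect_lt(max(abs(base[inner] - oracle[inner])), 1e-3)
})

test_that("detrending reconstructs the input exactly and is idempotent", {
  t <- (0:23999) / fs
  raw <- tibble::tibble(time_s = t, z = 212.2 + 2 * sin(2 * pi * 0.05 * t) +
                          0.2 * sin(2 * pi * 1.2 * t))
  sig <- detrend_reg(raw)
  expect_equal(sig$q + sig$baseline, raw$z, tolerance = 1e-9)
  interior <- t >= 8 & t <= max(t) - 8
  expect_lt(max(abs((sig$q - 0.2 * sin(2 * pi * 1.2 * t))[interior])), 0.01 * 0.2)
  # re-detrending changes almost nothing
  sig2 <- detrend_reg(tibble::tibble(time_s = t, z = sig$q))
  expect_lt(max(abs(sig2$q - sig$q)), 1e-3)
  # constant input -> zero REG
  const <- detrend_reg(tibble::tibble(time_s = t, z = rep(5, length(t))))
  expect_equal(const$q, rep(0, length(t)), tolerance = 1e-12)
})

test_that("zero-phase filtering commutes with time reversal", {
  withr::with_seed(3, {
    t <- (0:11999) / fs
    x <- 2 * sin(2 * pi * 0.07 * t + 1) + 0.3 * sin(2 * pi * 1.3 * t) + rnorm(12000, 0, 0.01)
  })
  fwd <- extract_baseline(tibble::tibble(time_s = t, z = x))$baseline
  bwd <- extract_baseline(tibble::tibble(time_s = t, z = rev(x)))$baseline
  expect_equal(rev(bwd), fwd, tolerance = 1e-7)
})

test_that("cycle detection finds a clean 75 bpm train with trough boundaries", {
  train <- pulse_train(60, hr = 75, fs = fs)
  cyc <- detect_cycles(train)
  acc <- cyc[cyc$accepted, ]
  expect_gte(nrow(acc), 59)
  expect_lte(nrow(acc), 61)
  expect_equal(median(acc$duration_s), 0.8, tolerance = 0.02)
  expect_true(all(acc$start_idx <= acc$peak_idx & acc$peak_idx < acc$end_idx))
  expect_equal(acc$duration_s, (acc$end_idx - acc$start_idx) / fs)
})

test_that("a low-amplitude cycle is rejected by the amplitude screen", {
  amps <- rep(1, 60)
  amps[30] <- 0.2
  cyc <- detect_cycles(pulse_train(60, amps = amps))
  acc <- cyc[cyc$accepted, ]
  expect_gte(nrow(acc), 58)
  expect_lte(nrow(acc), 60)
  # the small cycle (around t = 29*0.8 s) is not among the accepted ones
  small <- which(cyc$start_s < 29 * 0.8 & cyc$end_s > 29.5 * 0.8)
  expect_false(any(cyc$accepted[small]))
})

test_that("a single-sample spike rejects only its enclosing cycle", {
  train <- pulse_train(60)
  spike_at <- which.min(abs(train$time_s - 29.95 * 0.8))
  train$q[spike_at] <- train$q[spike_at] + 5
  cyc <- detect_cycles(train)
  acc <- cyc[cyc$accepted, ]
  expect_gte(nrow(acc), 58)
  hit <- cyc$start_idx <= spike_at & cyc$end_idx > spike_at
  expect_false(any(cyc$accepted[hit]))

  expect_error(detect_cycles(tibble::tibble(time_s = (0:999) / fs, q = rep(0, 1000))),
               "no pulse peaks")
})

test_that("cubic-spline time normalization matches closed forms", {
  # half-sine of 100 samples resampled to M = 160
  L <- 100
  sig <- tibble::tibble(time_s = (0:(L)) / fs, q = sin(pi * (0:L) / L))
  cyc <- manual_cycles(starts = 1L, ends = L + 1L, peaks = 51L, fs = fs)
  norm <- normalize_cycles(cyc, sig, M = 160)
  expect_equal(nrow(norm), 160)
  expect_lt(max(abs(norm$q - sin(pi * norm$phase))), 1e-3)

  # a cycle already of length M passes through unchanged
  norm_same <- normalize_cycles(cyc, sig, M = 100)
  expect_equal(norm_same$q, sig$q[1:100], tolerance = 1e-9)

  # different-length cycles both come out at M
  sig2 <- tibble::tibble(time_s = (0:300) / fs,
                         q = c(sin(pi * (0:99) / 100), sin(pi * (0:150) / 151), rep(0, 50)))
  cyc2 <- manual_cycles(starts = c(1L, 101L), ends = c(101L, 252L),
                        peaks = c(51L, 176L), fs = fs)
  norm2 <- normalize_cycles(cyc2, sig2, M = 120)
  expect_equal(as.integer(table(norm2$cycle)), c(120L, 120L))
})

test_that("template averaging preserves identical cycles and cancels noise", {
  M <- 160
  phase <- (0:(M - 1)) / M
  w <- sin(pi * phase)^1.5 + 0.3 * sin(2 * pi * phase + 0.4)
  identical_cycles <- purrr::map_dfr(1:5, ~ tibble::tibble(cycle = .x, phase = phase, q = w))
  attr(identical_cycles, "mean_period") <- 0.8
  tmpl <- build_template(identical_cycles)
  expect_equal(tmpl$w, w)
  expect_equal(tmpl$n_cycles, 5)
  expect_equal(tmpl$mean_period, 0.8)
  expect_equal(cor(tmpl$w, tmpl$w), 1)

  # w and -w average to zero
  pm <- dplyr::bind_rows(tibble::tibble(cycle = 1, phase = phase, q = w),
                         tibble::tibble(cycle = 2, phase = phase, q = -w))
  expect_equal(build_template(pm)$w, rep(0, M))

  # 50 noisy copies: RMS error < sigma/sqrt(50) * 1.5
  sigma <- 0.05
  withr::with_seed(9, {
    noisy <- purrr::map_dfr(1:50, ~ tibble::tibble(cycle = .x, phase = phase,
                                                   q = w + rnorm(M, 0, sigma)))
  })
  tmpl_n <- build_template(noisy)
  expect_lt(sqrt(mean((tmpl_n$w - w)^2)), sigma / sqrt(50) * 1.5)

  expect_error(build_template(tibble::tibble(cycle = 1, phase = phase, q = w)),
               "at least 2")
})

test_that("the template recovers the generator's clean morphology", {
  sp <- synth_params(perturb_cycles = 0, noise_sigma = 0.005, seed = 4)
  sc <- gen_recovery_scenario(sp)
  sig <- detrend_reg(sc$reg)
  tmpl <- standardize_waveform(sig, baseline_s = 60)
  clean <- regcar:::pulse_shape((tmpl$phase), "reg")
  expect_gt(cor(tmpl$w, clean - mean(clean)), 0.999)
  expect_gte(tmpl$n_cycles, 50)
})
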