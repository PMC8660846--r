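wt <- make_preset("wt_embryo")
mut <- make_preset("r14del_embryo")

# toy pure-decay transient: D + A*exp(-t/tau), segment starting at the peak
pure_decay_trace <- function(tau, fs = 1000, dia = 10, amp = 50,
                             dur_ms = 6 * tau) {
  t <- seq(0, dur_ms, by = 1000 / fs)
  uniform_trace(dia + amp * exp(-t / tau), fs = fs)
}

test_that("a constant trace yields no transients", {
  tr <- uniform_trace(rep(5, 100), fs = 100)
  expect_length(detect_transients(tr), 0)
})

test_that("two merged peaks closer than the separation yield one segment", {
  # brute-force toy: two bumps 40 ms apart at 1 kHz
  t <- seq(0, 200, by = 1)
  x <- exp(-(t - 80)^2 / 50) + 0.8 * exp(-(t - 120)^2 / 50)
  tr <- uniform_trace(x, fs = 1000)
  expect_length(detect_transients(tr, min_separation_ms = 100), 1)
  expect_length(detect_transients(tr, min_separation_ms = 10), 2)
})

test_that("pure-decay closed forms: cad50 = tau ln2, recovery = tau ln10", {
  tau <- 100
  tr <- pure_decay_trace(tau)
  seg <- list(start = 1L, peak = 1L, end = length(tr$samples))
  f <- transient_features(tr, seg, diastolic = 10)
  expect_equal(f$cad50, tau * log(2), tolerance = 1e-3)
  expect_equal(f$recovery_time, tau * log(10), tolerance = 1e-3)
  expect_equal(f$amplitude, 50, tolerance = 1e-9)
  expect_true(f$cad20 <= f$cad50 && f$cad50 <= f$cad80)
})

test_that("noiseless generator round-trip recovers the preset to < 0.1%", {
  for (p in list(wt, mut)) {
    tr <- gen_calcium_train(p, n_beats = 10, fs = 100, noise_sd = 0)
    segs <- detect_transients(tr)
    for (seg in segs) {
      f <- transient_features(tr, seg, frequency = attr(segs, "frequency"))
      expect_equal(f$amplitude, p$amplitude, tolerance = 1e-3)
      # with overlapping tails the decay asymptote sits below the pre-onset
      # baseline; the asymptote-refined fit recovers tau on every beat
      tau_fit <- fit_decay_tau(tr, seg, asymptote = "fit")
      expect_equal(tau_fit, p$tau_decay, tolerance = 1e-3)
    }
    # first beat has a clean lead-in baseline: exact diastolic and tau
    f1 <- transient_features(tr, segs[[1]])
    expect_equal(f1$diastolic, p$diastolic_level, tolerance = 1e-9)
    expect_equal(f1$tau, p$tau_decay, tolerance = 1e-9)
  }
})

test_that("cad ordering holds on every generated preset", {
  for (nm in c("wt_embryo", "r14del_embryo", "wt_adult")) {
    p <- make_preset(nm)
    fs <- if (grepl("adult", nm)) 1000 else 100
    tr <- gen_calcium_train(p, n_beats = 3, fs = fs, seed = 7)
    segs <- detect_transients(tr)
    for (seg in segs) {
      f <- transient_features(tr, seg)
      expect_true(f$cad20 <= f$cad50 && f$cad50 <= f$cad80)
    }
  }
})

test_that("tau fit is offset-invariant and time-scale equivariant", {
  tr <- gen_calcium_train(wt, n_beats = 1, fs = 100, noise_sd = 0)
  seg <- detect_transients(tr)[[1]]
  tau0 <- fit_decay_tau(tr, seg)
  shifted <- uniform_trace(tr$samples + 123.4, fs = tr$fs, t0 = tr$t0)
  expect_equal(fit_decay_tau(shifted, seg), tau0, tolerance = 1e-9)
  # doubling tau doubles the fit: simulate with halved sampling rate
  slower <- uniform_trace(tr$samples, fs = tr$fs / 2, t0 = tr$t0)
  expect_equal(fit_decay_tau(slower, seg), 2 * tau0, tolerance = 1e-9)
})

test_that("tau fit under 2% noise is unbiased within 3% over 50 seeds", {
  taus <- vapply(1:50, function(s) {
    tr <- gen_calcium_train(wt, n_beats = 1, fs = 100, seed = s,
                            noise_sd = 0.02 * wt$amplitude)
    segs <- detect_transients(tr)
    fit_decay_tau(tr, segs[[1]])
  }, numeric(1))
  expect_equal(mean(taus), wt$tau_decay, tolerance = 0.03)
})

test_that("tau fit guards against degenerate windows", {
  tr <- pure_decay_trace(100, fs = 20, dur_ms = 200) # few samples
  seg <- list(start = 1L, peak = 1L, end = 3L)
  expect_error(fit_decay_tau(tr, seg, diastolic = 10), "fewer than 5")
  rising <- uniform_trace(seq(10, 60, length.out = 50), fs = 100)
  seg2 <- list(start = 1L, peak = 50L, end = 50L)
  expect_error(transient_features(rising, seg2), NA) # upstroke-only is fine
})

test_that("amplitude normalization maps the reference mean to 100%", {
  res <- normalize_amplitudes(list(wt = c(90, 110), mut = c(60, 80)), "wt")
  expect_equal(mean(res$wt), 100)
  expect_equal(res$mut, c(60, 80))
  # within-group ratios preserved exactly
  expect_equal(res$mut[2] / res$mut[1], 80 / 60)
  same <- normalize_amplitudes(list(a = c(5, 5), b = c(5, 5)), "a")
  expect_equal(unlist(same), rep(100, 4), ignore_attr = TRUE)
  expect_error(normalize_amplitudes(list(a = 0, b = 1), "a"), "zero")
  expect_error(normalize_amplitudes(list(a = numeric(0), b = 1), "a"), "empty")
})

test_that("the printed group means give a 26% amplitude reduction", {
  norm <- normalize_amplitudes(list(wt = 99.8, mut = 73.9), "wt")
  expect_equal(round(percent_change(mean(norm$wt), mean(norm$mut))), 26)
})

test_that("Indo-1 conversion follows the ratio equation and inverts", {
  cal <- indo1_calibration(kd = 250, rmin = 0.5, rmax = 2.5, beta = 3)
  expect_equal(indo1_to_ca(cal$rmin, cal), 0)
  expect_equal(indo1_to_ca((cal$rmin + cal$rmax) / 2, cal), cal$kd * cal$beta)
  r <- seq(0.6, 2.4, by = 0.2)
  ca <- indo1_to_ca(r, cal)
  expect_true(all(diff(ca) > 0))
  # independent algebraic inverse: solve kd*b*(r - rmin)/(rmax - r) = ca for r
  r_back <- (cal$rmin * cal$kd * cal$beta + ca * cal$rmax) /
    (cal$kd * cal$beta + ca)
  expect_equal(r_back, r, tolerance = 1e-12)
  expect_equal(ca_to_indo1(ca, cal), r, tolerance = 1e-12)
  expect_error(indo1_to_ca(3, cal), "calibration")
  expect_error(indo1_calibration(rmin = 2, rmax = 1), "rmax > rmin")
})

test_that("averaging identical noiseless beats reproduces a single beat", {
  # slow pacing so the decay completes and all beats are truly identical
  p <- preset_with(wt, beat_rate = 0.5)
  tr <- gen_calcium_train(p, n_beats = 12, fs = 100, noise_sd = 0)
  segs <- detect_transients(tr, min_separation_ms = 500)
  avg <- average_transients(tr, segs, n = 10)
  one <- average_transients(tr, segs, n = 1)
  m <- min(length(avg$samples), length(one$samples))
  expect_equal(avg$samples[1:m], one$samples[1:m], tolerance = 1e-6)
  expect_error(average_transients(tr, segs, n = 13), "12 transient")
})

test_that("averaging 10 noisy transients reduces noise by about sqrt(10)", {
  sds <- vapply(1:15, function(s) {
    noisy <- gen_calcium_train(wt, n_beats = 12, fs = 100, seed = s,
                               noise_sd = 5)
    clean <- gen_calcium_train(wt, n_beats = 12, fs = 100, noise_sd = 0)
    segs <- detect_transients(clean) # common segmentation
    a_n <- average_transients(noisy, segs, n = 10)
    a_c <- average_transients(clean, segs, n = 10)
    stats::sd(a_n$samples - a_c$samples)
  }, numeric(1))
  expect_equal(mean(sds), 5 / sqrt(10), tolerance = 0.25)
})
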