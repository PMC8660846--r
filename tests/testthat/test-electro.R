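test_that("segmentation yields one segment per stimulus", {
  burst <- gen_ap_train(pacing = 3, n_aps = 20, apd90_even = 150, fs = 5000)
  expect_length(segment_aps(burst$trace, burst$stimuli), 20)
  empty <- stimulus_train(numeric(0), 1)
  expect_length(segment_aps(burst$trace, empty), 0)
  train <- gen_ap_train(pacing = 1, n_aps = 12, fs = 5000, post_ms = 100)
  segs <- segment_aps(train$trace, train$stimuli)
  expect_length(segs, 12)
  durs <- vapply(segs[-12], function(s) (s$end - s$start + 1) / 5, numeric(1))
  expect_true(all(abs(durs - 1000) <= 1))
  bad <- stimulus_train(1e6, 1)
  expect_error(segment_aps(train$trace, bad), "outside")
})

test_that("controlled AP features are recovered from noiseless trains", {
  ap <- gen_ap_train(rmp = -75, apa = 110, plateau_frac = 0.75,
                     apd90_even = 150, pacing = 1, n_aps = 3, fs = 40000)
  segs <- segment_aps(ap$trace, ap$stimuli)
  for (seg in segs) {
    f <- ap_features(ap$trace, seg)
    expect_equal(f$rmp, -75, tolerance = 1e-6)
    expect_equal(f$apa_max, 110, tolerance = 1e-6)
    expect_equal(f$apd90, 150, tolerance = 0.05) # within 1-2 samples at 40 kHz
    expect_equal(f$apa_plat, 0.75 * 110, tolerance = 0.5)
    expect_true(f$apd20 <= f$apd50 && f$apd50 <= f$apd90)
    expect_gt(f$dvdt_max, 100)
  }
})

test_that("APD ordering holds across a range of generated APs", {
  for (apd in c(80, 120, 200)) {
    ap <- gen_ap_train(apd90_even = apd, pacing = 2, n_aps = 2, fs = 20000)
    f <- ap_features(ap$trace, segment_aps(ap$trace, ap$stimuli)[[1]])
    expect_true(f$apd20 <= f$apd50 && f$apd50 <= f$apd90)
    expect_equal(f$apd90, apd, tolerance = 0.1)
  }
})

test_that("a linear repolarization ramp of -1 V/s gives phase3_vmax = 1", {
  # toy segment: instant upstroke then a pure -1 mV/ms ramp back to rest
  fs <- 10000
  up <- seq(-75, 35, length.out = 21)
  ramp <- seq(35, -85, by = -1 * 1000 / fs) # -1 V/s
  x <- c(rep(-75, 50), up, ramp)
  tr <- uniform_trace(x, fs = fs)
  f <- ap_features(tr, list(start = 1L, end = length(x)))
  expect_equal(f$phase3_vmax, 1, tolerance = 1e-6)
})

test_that("AP feature averaging follows the 10-beat convention", {
  rec <- data.frame(rmp = -75, apa_max = 110, apa_plat = 80, apd20 = 50,
                    apd50 = 100, apd90 = 150, dvdt_max = 170,
                    phase3_vmax = 1.1)
  ten <- do.call(rbind, replicate(10, rec, simplify = FALSE))
  expect_equal(as.numeric(average_ap_features(ten)), as.numeric(rec))
  alt <- ten
  alt$apd90 <- rep(c(120, 80), 5)
  expect_equal(average_ap_features(alt)$apd90, 100)
  expect_warning(avg7 <- average_ap_features(ten[1:7, ]), "only 7")
  expect_equal(avg7$apd90, 150)
  expect_error(average_ap_features(rec[0, ]), "no AP feature")
})

test_that("the alternans statistic is the mean absolute APD90 difference", {
  expect_equal(apd_alternans(rep(150, 8))$mean_abs_diff, 0)
  expect_equal(apd_alternans(c(120, 80, 120, 80))$mean_abs_diff, 40)
  a <- apd_alternans(c(100, 110, 90))
  expect_equal(a$mean_abs_diff, 15)
  expect_equal(a$n_pairs, 2)
  expect_equal(a$per_pair_diffs, c(10, 20))
  # reversing the series preserves the statistic
  s <- c(132, 95, 141, 102, 128)
  expect_equal(apd_alternans(rev(s))$mean_abs_diff,
               apd_alternans(s)$mean_abs_diff)
  expect_error(apd_alternans(100), "at least 2")
})

test_that("alternans measured end-to-end equals |even - odd| APD90", {
  ap <- gen_ap_train(apd90_even = 120, apd90_odd = 80, pacing = 4,
                     n_aps = 8, fs = 20000)
  segs <- segment_aps(ap$trace, ap$stimuli)
  apds <- vapply(segs, function(s) ap_features(ap$trace, s)$apd90, numeric(1))
  expect_equal(apd_alternans(apds)$mean_abs_diff, 40, tolerance = 0.01)
})

test_that("DAD detection applies the >1 mV rule in the post-burst pause", {
  win_for <- function(ap) {
    last <- max(ap$stimuli$times)
    c(last + 700, last + 7000)
  }
  with_dad <- gen_ap_train(n_aps = 20, pacing = 3, apd90_even = 150,
                           post_ms = 8000, dad = list(delay = 1500, amp = 2),
                           fs = 2000)
  ev <- detect_dads(with_dad$trace, win_for(with_dad))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 2, tolerance = 0.01)
  small <- gen_ap_train(n_aps = 20, pacing = 3, apd90_even = 150,
                        post_ms = 8000, dad = list(delay = 1500, amp = 0.5),
                        fs = 2000)
  expect_equal(nrow(detect_dads(small$trace, win_for(small))), 0)
  flat <- gen_ap_train(n_aps = 20, pacing = 3, apd90_even = 150,
                       post_ms = 8000, fs = 2000)
  expect_equal(nrow(detect_dads(flat$trace, win_for(flat))), 0)
})

test_that("DAD detection has no false positives on 100 noise-only traces", {
  fp <- vapply(1:100, function(s) {
    a <- gen_ap_train(n_aps = 3, pacing = 3, apd90_even = 150,
                      post_ms = 3000, noise_sd = 0.2, seed = s, fs = 1000)
    last <- max(a$stimuli$times)
    nrow(detect_dads(a$trace, c(last + 700, last + 2800)))
  }, numeric(1))
  expect_equal(sum(fp), 0)
})

test_that("K+ current partition splits at -30 mV and conserves rows", {
  iv <- data.frame(v_mV = seq(-120, 40, by = 10),
                   i_pA = seq(-120, 40, by = 10) * 2)
  parts <- partition_k_currents(iv)
  expect_equal(nrow(parts$ik1), 9)
  expect_equal(nrow(parts$ikr), 7)
  boundary <- sum(iv$v_mV == -30)
  expect_equal(nrow(parts$ik1) + nrow(parts$ikr) + boundary, nrow(iv))
  allpos <- data.frame(v_mV = c(0, 10, 20), i_pA = c(1, 2, 3))
  expect_equal(nrow(partition_k_currents(allpos)$ik1), 0)
  expect_error(partition_k_currents(data.frame(v_mV = c(0, 0), i_pA = 1:2)),
               "duplicate")
})

test_that("I_Ca,L is peak minus steady state, normalized by capacitance", {
  step <- uniform_trace(c(-400, rep(-100, 99)), fs = 5000, units = "pA")
  res <- ical_two_pulse(step, cm = 20)
  expect_equal(res$i_cal, -300)
  expect_equal(res$density, -15)
  expect_equal(ical_two_pulse(step, cm = 40)$i_cal, -300)
  expect_equal(ical_two_pulse(step, cm = 40)$density, -7.5)
  flat <- uniform_trace(rep(-100, 100), fs = 5000, units = "pA")
  expect_equal(ical_two_pulse(flat, cm = 20)$i_cal, 0)
  expect_error(ical_two_pulse(step, cm = 0), "positive")
})

test_that("membrane capacitance follows tau / Rs with unit bookkeeping", {
  expect_equal(estimate_cm(1, 5)$cm, 200)
  expect_equal(estimate_cm(0.5, 5)$cm, 100)
  est <- estimate_cm(1.3, 4.2)
  expect_equal(est$cm / 1000 * est$rs, est$tau_cap, tolerance = 1e-12)
  expect_error(estimate_cm(-1, 5), "positive")
  expect_error(estimate_cm(1, 0), "positive")
})
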