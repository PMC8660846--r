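test_that("outflow-tract area and Doppler stroke volume follow the formulas", {
  expect_equal(vot_area(2), pi)
  expect_equal(vot_area(1), pi / 4)
  expect_equal(vot_area(2 * 1.7), 4 * vot_area(1.7)) # quadratic in d
  expect_error(vot_area(0), "positive")

  res <- doppler_stroke_volume(10, pi, 100)
  expect_equal(res$sv, 31.41593, tolerance = 1e-6)
  expect_equal(res$co, 3.141593, tolerance = 1e-6)
  expect_equal(doppler_stroke_volume(20, pi, 100)$sv, 2 * res$sv)
  expect_equal(doppler_stroke_volume(10, 2 * pi, 100)$sv, 2 * res$sv)
  expect_error(doppler_stroke_volume(10, 0, 100), "positive")
})

test_that("peak-velocity variation is the normalized mean beat-to-beat step", {
  expect_equal(pv_variation(rep(9, 8)), 0)
  b <- gen_beat_series(9, 2 / 9, 6)
  expect_equal(b$pv, c(10, 8, 10, 8, 10, 8))
  expect_equal(pv_variation(b), 2 / 9)
  expect_equal(pv_variation(3 * b$pv), pv_variation(b$pv)) # scale-invariant
  expect_error(pv_variation(c(10, 8, 10, 8, 10)), "at least 6")
  expect_error(gen_beat_series(9, 2.5, 6), "variation")
  expect_error(gen_beat_series(9, 0.1, 5), "6 beats")
  r1 <- gen_beat_series(9, 0.2, 10, mode = "random", seed = 5)
  r2 <- gen_beat_series(9, 0.2, 10, mode = "random", seed = 5)
  expect_identical(r1$pv, r2$pv)
})

test_that("alternating-mode variation equals the generator parameter", {
  for (v in c(0, 0.1, 0.3)) {
    b <- gen_beat_series(12, v, 8)
    expect_equal(pv_variation(b), v, tolerance = 1e-12)
  }
})

test_that("ellipse area and volume match the model formulas", {
  d <- 37
  sphere <- ellipse_area_volume(d, d)
  expect_equal(sphere$volume, (pi / 6) * d^3 / 1000)
  unit <- ellipse_area_volume(6 / pi, 1)
  expect_equal(unit$volume, 1 / 1000) # 1 um^3 = 1e-3 pL
  hand <- ellipse_area_volume(100, 50)
  expect_equal(hand$area, pi * 100 * 50 / 4)
  expect_equal(hand$volume, 130.8997, tolerance = 1e-6)
  expect_warning(sw <- ellipse_area_volume(50, 100), "swapping")
  expect_equal(sw$volume, hand$volume)
})

test_that("formulas agree with numerical integration on random axis pairs", {
  set.seed(11)
  for (i in 1:10) {
    a <- stats::runif(1, 40, 160)
    b <- stats::runif(1, 20, a)
    got <- ellipse_area_volume(a, b)
    # slice the ellipse/ellipsoid along the major axis
    u <- seq(-a / 2, a / 2, length.out = 20001)
    half_width <- (b / 2) * sqrt(pmax(0, 1 - (2 * u / a)^2))
    area_num <- sum(2 * half_width) * (u[2] - u[1])
    vol_num <- sum(pi * half_width^2) * (u[2] - u[1]) / 1000
    expect_equal(got$area, area_num, tolerance = 5e-3)
    expect_equal(got$volume, vol_num, tolerance = 5e-3)
  }
})

test_that("series volumetrics recover a designed ejection fraction", {
  f <- 0.5^(1 / 3) # uniform axis scaling halving the volume
  es <- gen_ellipse_series(120, 90, 120 * f, 90 * f, hr = 120, fps = 150,
                           n_cycles = 6)
  v <- volumetrics_from_series(es)
  expect_equal(v$ef, 0.5, tolerance = 0.02)
  expect_equal(v$sv, v$edv - v$esv, tolerance = 1e-9)
  expect_equal(v$co, v$sv * v$hr, tolerance = 1e-9)
  expect_equal(v$hr, 120, tolerance = 0.02)
  expect_error(volumetrics_from_series(
    gen_ellipse_series(120, 90, 120 * f, 90 * f, 120, 150, 2)),
    "at least 3")
  expect_error(gen_ellipse_series(100, 80, 110, 70, 120, 150, 3),
               "axes")
  expect_error(gen_ellipse_series(100, 80, 99, 79, 500, 20, 3), "frames")
})

test_that("contraction and relaxation timing partition the cycle", {
  fs <- 150
  t <- seq(0, 3, by = 1 / fs)
  sine <- 2 + cos(2 * pi * t) # 1 s cycle, starts at end-diastole
  ct <- contraction_timing(sine, fs)
  expect_equal(ct$contraction_ms, 500, tolerance = 10)
  expect_equal(ct$relaxation_ms, 500, tolerance = 10)
  expect_equal(ct$contraction_ms + ct$relaxation_ms, ct$cycle_ms)
  # sawtooth: fall in 250 ms, rise in 750 ms
  one <- c(seq(2, 1, length.out = round(0.25 * fs) + 1)[-1],
           seq(1, 2, length.out = round(0.75 * fs) + 1)[-1])
  saw <- c(2, rep(one, 3))
  cs <- contraction_timing(saw, fs)
  expect_equal(cs$contraction_ms, 250, tolerance = 8)
  expect_equal(cs$relaxation_ms, 750, tolerance = 8)
  expect_equal(cs$cycle_ms, 1000, tolerance = 8)
  expect_error(contraction_timing(rep(1, 100), fs), "flat")
})

test_that("moment-based axes recover rendered shapes within 2%", {
  n <- 121
  d <- matrix(FALSE, n, n)
  ctr <- (n + 1) / 2
  disc <- (row(d) - ctr)^2 + (col(d) - ctr)^2 <= 50^2
  ad <- ellipse_from_mask(disc)
  expect_equal(ad$major, 100, tolerance = 0.02)
  expect_equal(ad$minor, 100, tolerance = 0.02)

  masks <- render_ellipse_movie(ellipse_series(120, 60, fs = 1))
  ae <- ellipse_from_mask(masks[[1]])
  expect_equal(ae$major, 120, tolerance = 0.02)
  expect_equal(ae$minor, 60, tolerance = 0.02)

  one_px <- matrix(FALSE, 10, 10); one_px[5, 5] <- TRUE
  expect_error(ellipse_from_mask(one_px), "degenerate")
  expect_error(ellipse_from_mask(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 30, 30)
  two[2:8, 2:8] <- TRUE; two[20:26, 20:26] <- TRUE
  expect_error(ellipse_from_mask(two), "one connected component")
})

test_that("movie render/read/measure round-trips the ejection fraction", {
  f <- 0.5^(1 / 3)
  es <- gen_ellipse_series(120, 90, 120 * f, 90 * f, hr = 120, fps = 150,
                           n_cycles = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  render_ellipse_movie(es, path = path)
  masks <- read_ellipse_movie(path)
  expect_length(masks, nrow(es))
  es2 <- ellipse_series_from_masks(masks, fs = 150)
  v <- volumetrics_from_series(es2)
  expect_equal(v$ef, 0.5, tolerance = 0.03)
})
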