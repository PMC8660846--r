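#' Ventricular outflow tract cross-section
#'
#' Circular outflow surface from the manually measured tract diameter:
#' `pi * (d/2)^2`.
#'
#' @param diameter Outflow tract diameter (mm, > 0).
#' @return Area in mm^2.
#' @export
vot_area <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be positive", call. = FALSE)
  pi * (diameter / 2)^2
}

#' Doppler stroke volume and cardiac output
#'
#' Stroke volume is the outflow velocity-time integral multiplied by the
#' outflow surface (mm^3 = ul); cardiac output multiplies by heart rate and
#' is reported in ml/min.
#'
#' @param vti Velocity-time integral (mm, > 0).
#' @param area Outflow surface (mm^2, > 0), e.g. from [vot_area()].
#' @param hr Heart rate (bpm, > 0).
#' @return `list(sv = <ul>, co = <ml/min>)`.
#' @export
doppler_stroke_volume <- function(vti, area, hr) {
  if (any(c(vti, area, hr) < 0) || area == 0 || hr == 0) {
    stop("vti, area and hr must be positive", call. = FALSE)
  }
  sv <- vti * area
  list(sv = sv, co = sv * hr / 1000)
}

#' Beat-to-beat peak-velocity variation
#'
#' Mean absolute difference in outflow peak velocity between consecutive
#' beats, corrected for (divided by) the mean peak velocity of the fish —
#' a dimensionless coefficient of beat-to-beat variability that is invariant
#' to rescaling all velocities.
#'
#' @param beats A [gen_beat_series()] table (or any data frame with a `pv`
#'   column, or a plain numeric vector of peak velocities).
#' @param min_beats Minimum number of beats required (6 by convention).
#' @return The variation statistic (dimensionless fraction).
#' @export
pv_variation <- function(beats, min_beats = 6) {
  pv <- if (is.data.frame(beats)) beats$pv else as.numeric(beats)
  if (is.null(pv)) stop("beat table lacks a `pv` column", call. = FALSE)
  if (length(pv) < min_beats) {
    stop(sprintf(
      "only %d beats; the variability statistic requires at least %d beats per fish",
      length(pv), min_beats), call. = FALSE)
  }
  if (any(pv <= 0)) stop("peak velocities must be positive", call. = FALSE)
  mean(abs(diff(pv))) / mean(pv)
}

#' Ellipse-model area and volume of the embryonic ventricle
#'
#' Projected surface area `pi * a * b / 4` (um^2) and prolate-ellipsoid
#' volume `(pi/6) * a * b^2` (um^3, converted to pL; 1000 um^3 = 1 pL) from
#' the major and minor axes of the fitted ellipse.
#'
#' @param major,minor Ellipse axes in um. If a pair arrives in the wrong
#'   order it is swapped with a warning.
#' @return `list(area = <um^2>, volume = <pL>)`, vectorized over the axes.
#' @export
ellipse_area_volume <- function(major, minor) {
  stopifnot(length(major) == length(minor), all(major > 0), all(minor > 0))
  swap <- major < minor
  if (any(swap)) {
    warning("major < minor for some frames; swapping axis order", call. = FALSE)
    tmp <- major[swap]
    major[swap] <- minor[swap]
    minor[swap] <- tmp
  }
  list(area = pi * major * minor / 4,
       volume = (pi / 6) * major * minor^2 / 1000)
}

#' Volumetrics from an ellipse axis series
#'
#' Converts per-frame axes to volumes, finds the per-cycle volume extrema on
#' a lightly smoothed series (moving average of width `fs / 10`, mirroring
#' manual end-diastole/end-systole frame selection), and summarizes:
#' EDV = mean of the `n_per_phase` largest per-cycle maxima, ESV = mean of
#' the `n_per_phase` smallest per-cycle minima, SV = EDV - ESV,
#' EF = SV / EDV, heart rate from the cycle count over the recording span,
#' CO = SV x HR.
#'
#' @param series An [ellipse_series()].
#' @param n_per_phase Number of diastolic and systolic frames averaged
#'   (3 + 3 by convention).
#' @return Object of class `volumetrics`: `edv`, `esv`, `sv` (pL), `ef`
#'   (fraction), `hr` (bpm), `co` (pL/min), `n_cycles`.
#' @export
volumetrics_from_series <- function(series, n_per_phase = 3) {
  stopifnot(inherits(series, "ellipse_series"))
  fs <- attr(series, "fs")
  vol <- ellipse_area_volume(series$major, series$minor)$volume
  sm <- moving_average(vol, max(1L, round(fs / 10)))
  rng <- diff(range(sm))
  if (rng <= 0) stop("flat volume series; no cardiac cycles", call. = FALSE)
  maxima <- find_prominent_peaks(sm, 0.3 * rng, 2L)
  minima <- find_prominent_peaks(-sm, 0.3 * rng, 2L)
  # include boundary extremes: series generated at end-diastole start there
  if (length(sm) && which.max(sm) %in% c(1L, length(sm))) {
    maxima <- sort(unique(c(maxima, which.max(sm))))
  }
  n_cycles <- min(length(maxima), length(minima))
  if (n_cycles < n_per_phase) {
    stop(sprintf("only %d cardiac cycle(s) detected; need at least %d",
                 n_cycles, n_per_phase), call. = FALSE)
  }
  edv <- mean(sort(vol[maxima], decreasing = TRUE)[seq_len(n_per_phase)])
  esv <- mean(sort(vol[minima])[seq_len(n_per_phase)])
  sv <- edv - esv
  span_min <- (series$time_ms[length(vol)] - series$time_ms[1]) / 60000
  hr <- if (length(maxima) >= 2L) {
    (length(maxima) - 1) /
      ((series$time_ms[maxima[length(maxima)]] - series$time_ms[maxima[1]]) / 60000)
  } else {
    length(minima) / span_min
  }
  structure(list(edv = edv, esv = esv, sv = sv, ef = sv / edv,
                 hr = hr, co = sv * hr, n_cycles = n_cycles),
            class = "volumetrics")
}

#' @export
print.volumetrics <- function(x, ...) {
  cat(sprintf(paste0("volumetrics: EDV %.4g pL, ESV %.4g pL, SV %.4g pL, ",
                     "EF %.3f, HR %.4g bpm, CO %.4g pL/min (%d cycles)\n"),
              x$edv, x$esv, x$sv, x$ef, x$hr, x$co, x$n_cycles))
  invisible(x)
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  f <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  ifelse(is.na(f), x, f)
}

#' Contraction and relaxation timing from a volume series
#'
#' Per cycle, the contraction time runs from a volume maximum (most dilated,
#' start of inward wall motion) to the following minimum (maximal
#' contraction), and the relaxation time from that minimum to the next
#' maximum; values are averaged over up to `n_cycles_avg` complete cycles.
#' Contraction plus relaxation equals the cycle length by construction.
#'
#' @param volumes Per-frame volumes (any consistent unit).
#' @param fs Frame rate (Hz).
#' @param n_cycles_avg Number of complete cycles averaged (3 by convention).
#' @param smooth_w Moving-average width in frames applied before extremum
#'   detection (0 = none).
#' @return `list(contraction_ms, relaxation_ms, cycle_ms, n_cycles_used)`.
#' @export
contraction_timing <- function(volumes, fs, n_cycles_avg = 3, smooth_w = 0) {
  v <- as.numeric(volumes)
  if (smooth_w > 1) v <- moving_average(v, as.integer(smooth_w))
  rng <- diff(range(v))
  if (rng <= 0) stop("flat volume series; no cycles", call. = FALSE)
  maxima <- find_prominent_peaks(v, 0.3 * rng, 2L)
  minima <- find_prominent_peaks(-v, 0.3 * rng, 2L)
  if (1L %in% seq_along(v) && which.max(v) == 1L) maxima <- sort(c(1L, maxima))
  t <- (seq_along(v) - 1) * 1000 / fs
  cycles <- NULL
  for (m in minima) {
    prev_max <- maxima[maxima < m]
    next_max <- maxima[maxima > m]
    if (length(prev_max) && length(next_max)) {
      cycles <- rbind(cycles, c(contraction = t[m] - t[max(prev_max)],
                                relaxation = t[min(next_max)] - t[m]))
    }
  }
  if (is.null(cycles)) {
    stop("no complete contraction-relaxation cycle found", call. = FALSE)
  }
  use <- seq_len(min(nrow(cycles), n_cycles_avg))
  contraction <- mean(cycles[use, "contraction"])
  relaxation <- mean(cycles[use, "relaxation"])
  list(contraction_ms = contraction, relaxation_ms = relaxation,
       cycle_ms = contraction + relaxation, n_cycles_used = length(use))
}

#' Ellipse axes from a binary mask
#'
#' Axis lengths from the second central moments of the foreground pixel
#' coordinates: each full axis is `4 * sqrt(eigenvalue)` of the coordinate
#' covariance matrix, which is exact for a filled ellipse. The mask must
#' contain a single 4-connected foreground component of at least a few
#' pixels.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return `list(major = <px>, minor = <px>)`.
#' @export
ellipse_from_mask <- function(mask) {
  m <- mask > 0
  npx <- sum(m)
  if (npx == 0L) stop("empty mask", call. = FALSE)
  if (npx < 5L) stop("degenerate mask: too few foreground pixels", call. = FALSE)
  if (count_components(m) != 1L) {
    stop("mask must contain exactly one connected component", call. = FALSE)
  }
  idx <- which(m, arr.ind = TRUE)
  ev <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("degenerate mask: collinear pixels", call. = FALSE)
  list(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]))
}

# 4-connected component count by iterative flood fill.
count_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  nr <- nrow(m); nc <- ncol(m)
  for (start in which(m)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1L && d[1] <= nr && d[2] >= 1L && d[2] <= nc) {
          j <- (d[2] - 1L) * nr + d[1]
          if (m[j] && lab[j] == 0L) {
            lab[j] <- comp
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  comp
}

#' Axis series from a mask movie
#'
#' Applies [ellipse_from_mask()] to every frame and scales to um.
#'
#' @param masks List of logical matrices (e.g. from [read_ellipse_movie()]).
#' @param fs Frame rate (Hz).
#' @param um_per_px Spatial scale.
#' @return An [ellipse_series()].
#' @export
ellipse_series_from_masks <- function(masks, fs, um_per_px = 1) {
  ax <- vapply(masks, function(m) {
    a <- ellipse_from_mask(m)
    c(a$major, a$minor)
  }, numeric(2))
  ellipse_series(ax[1, ] * um_per_px, ax[2, ] * um_per_px, fs = fs)
}
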