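#' Detect calcium transients in a trace
#'
#' Finds one segment per transient. Candidate peaks are local maxima whose
#' topographic prominence exceeds `min_prominence` times the trace range;
#' peaks closer together than `min_separation_ms` are merged (the higher one
#' is kept, so two overlapping transients yield a single segment). Segment
#' boundaries are placed at the local minima bracketing each peak.
#'
#' @param trace A [uniform_trace()].
#' @param min_prominence Minimum peak prominence as a fraction of the trace
#'   range.
#' @param min_separation_ms Minimum peak-to-peak separation in ms.
#' @return An object of class `transient_segments`: a list of segments
#'   (`start`, `peak`, `end` sample indices) with attribute `frequency`, the
#'   transient frequency in Hz computed as (n-1) / (t_last_peak -
#'   t_first_peak). A flat trace yields an empty list, not an error.
#' @export
detect_transients <- function(trace, min_prominence = 0.3,
                              min_separation_ms = 100) {
  stopifnot(inherits(trace, "uniform_trace"))
  x <- trace$samples
  rng <- diff(range(x))
  empty <- structure(list(), class = "transient_segments", frequency = NA_real_)
  if (rng <= .Machine$double.eps * max(1, abs(max(x)))) return(empty)

  min_dist <- max(1L, round(min_separation_ms * trace$fs / 1000))
  peaks <- find_prominent_peaks(x, min_prominence * rng, min_dist)
  if (length(peaks) == 0L) return(empty)

  n <- length(x)
  segs <- vector("list", length(peaks))
  for (j in seq_along(peaks)) {
    lo <- if (j == 1L) 1L else peaks[j - 1L]
    hi <- if (j == length(peaks)) n else peaks[j + 1L]
    left <- x[lo:peaks[j]]
    # last index attaining the minimum: the closest bracketing trough
    start <- lo + max(which(left == min(left))) - 1L
    right <- x[peaks[j]:hi]
    end <- peaks[j] + which.min(right) - 1L
    segs[[j]] <- list(start = start, peak = peaks[j], end = end)
  }
  freq <- if (length(peaks) >= 2L) {
    tt <- trace_times(trace)[peaks]
    (length(peaks) - 1) / ((tt[length(tt)] - tt[1]) / 1000)
  } else NA_real_
  structure(segs, class = "transient_segments", frequency = freq)
}

#' @export
print.transient_segments <- function(x, ...) {
  cat(sprintf("transient_segments: %d transient(s), frequency %.4g Hz\n",
              length(x), attr(x, "frequency")))
  invisible(x)
}

# Local maxima filtered by topographic prominence and minimum distance
# (greedy, keeping higher peaks). Returns sorted indices.
find_prominent_peaks <- function(x, min_prom_abs, min_dist) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i + 1L] & x[i] >= x[i - 1L]]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    higher_l <- which(x[seq_len(p - 1L)] > x[p])
    lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
    base_l <- min(x[lo:(p - 1L)])
    higher_r <- which(x[(p + 1L):n] > x[p]) + p
    hi <- if (length(higher_r)) min(higher_r) - 1L else n
    base_r <- min(x[(p + 1L):hi])
    x[p] - max(base_l, base_r)
  }, numeric(1))
  cand <- cand[prom >= min_prom_abs]
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - p) >= min_dist)) keep <- c(keep, p)
  }
  sort(keep)
}

# Baseline (diastolic) estimate for one segment, from the trace samples in
# the `baseline_ms` window ending at the last pre-upstroke sample (the sample
# before the rising half-amplitude crossing). method = "linear" (default)
# fits a line through the window and evaluates it at the first upstroke
# sample, which removes the decay-slope bias when the previous transient's
# tail has not fully returned to baseline; "mean" is the plain window mean.
estimate_baseline <- function(trace, seg, baseline_ms = 30,
                              method = c("linear", "mean")) {
  method <- match.arg(method)
  x <- trace$samples
  b0 <- x[seg$start]
  half <- b0 + 0.5 * (x[seg$peak] - b0)
  rise <- seg$start:seg$peak
  above <- rise[x[rise] >= half]
  onset <- if (length(above)) max(seg$start, min(above) - 1L) else seg$start
  w <- max(1L, round(baseline_ms * trace$fs / 1000))
  idx <- max(1L, onset - w + 1L):onset
  dia <- if (method == "mean" || length(idx) < 3L) {
    mean(x[idx])
  } else {
    fit <- stats::lm.fit(cbind(1, idx), x[idx])
    sum(fit$coefficients * c(1, onset + 1L))
  }
  list(diastolic = dia, onset = onset)
}

#' Per-transient feature extraction
#'
#' Measures one transient segment: diastolic level (mean of the pre-onset
#' baseline window), amplitude (peak minus diastolic), upstroke time (10%-rise
#' crossing to peak), recovery time (peak to the `recovery_frac` return
#' towards diastolic), transient durations CaD20/50/80 (width at
#' `(1 - X) * amplitude` above diastolic, rising to falling crossing) and the
#' mono-exponential decay constant tau from [fit_decay_tau()]. Crossing times
#' are linearly interpolated between samples. A crossing that is never reached
#' inside the segment yields `NA`, not an error.
#'
#' @param trace A [uniform_trace()].
#' @param seg One segment from [detect_transients()].
#' @param recovery_frac Fractional return towards diastolic defining the
#'   recovery time (default 0.9, i.e. 90% recovery).
#' @param duration_fracs Recovery levels X at which transient durations are
#'   measured (defaults 0.2, 0.5, 0.8 for CaD20/50/80).
#' @param baseline_ms Width of the pre-onset baseline window in ms.
#' @param baseline_method `"linear"` (line through the baseline window
#'   evaluated at the upstroke instant; unbiased when the previous tail is
#'   still decaying) or `"mean"` (plain window mean).
#' @param frequency Optional transient frequency (Hz) to carry into the
#'   record, e.g. `attr(segs, "frequency")`.
#' @param diastolic Optional known baseline level, bypassing the pre-onset
#'   estimate (useful for segments that begin at the peak).
#' @return A one-row data frame of class `ca_features` with columns
#'   `frequency`, `diastolic`, `amplitude`, `upstroke_time`, `recovery_time`,
#'   `cad20`, `cad50`, `cad80`, `tau` (times in ms).
#' @export
transient_features <- function(trace, seg, recovery_frac = 0.9,
                               duration_fracs = c(0.2, 0.5, 0.8),
                               baseline_ms = 30, baseline_method = "linear",
                               frequency = NA_real_, diastolic = NULL) {
  stopifnot(inherits(trace, "uniform_trace"))
  x <- trace$samples
  t <- trace_times(trace)
  dia <- if (is.null(diastolic)) {
    estimate_baseline(trace, seg, baseline_ms, baseline_method)$diastolic
  } else {
    diastolic
  }
  peak_v <- x[seg$peak]
  amp <- peak_v - dia
  if (amp <= 0) stop("non-positive transient amplitude", call. = FALSE)

  t_peak <- t[seg$peak]
  rise_cross <- function(level) {
    cross_time(x, t, seg$start, seg$peak, level, rising = TRUE,
               fallback = t_peak)
  }
  fall_cross <- function(level) {
    cross_time(x, t, seg$peak, seg$end, level, rising = FALSE,
               fallback = NA_real_)
  }

  upstroke <- t_peak - rise_cross(dia + 0.1 * amp)
  rec_level <- peak_v - recovery_frac * amp
  recovery <- fall_cross(rec_level) - t_peak

  cads <- vapply(duration_fracs, function(X) {
    lev <- dia + (1 - X) * amp
    fall_cross(lev) - rise_cross(lev)
  }, numeric(1))

  tau <- tryCatch(
    fit_decay_tau(trace, seg, diastolic = dia),
    error = function(e) NA_real_
  )

  out <- data.frame(
    frequency = frequency, diastolic = dia, amplitude = amp,
    upstroke_time = upstroke, recovery_time = recovery,
    cad20 = cads[1], cad50 = cads[2], cad80 = cads[3], tau = tau
  )
  class(out) <- c("ca_features", "data.frame")
  out
}

# First crossing of `level` on [from, to], linearly interpolated. For a rising
# search the first sample at/above level is used; falling, the first at/below.
cross_time <- function(x, t, from, to, level, rising, fallback) {
  if (to <= from) return(fallback)
  idx <- from:to
  hit <- if (rising) which(x[idx] >= level) else which(x[idx] <= level)
  if (!length(hit)) return(fallback)
  i <- idx[min(hit)]
  if (i == from) return(t[i])
  x0 <- x[i - 1L]; x1 <- x[i]
  if (x1 == x0) return(t[i])
  t[i - 1L] + (level - x0) / (x1 - x0) * (t[i] - t[i - 1L])
}

#' Fit the mono-exponential decay constant of a transient
#'
#' Least squares on `log(signal - diastolic)` over the falling-limb samples
#' whose amplitude lies between `fit_window[1]` and `fit_window[2]` of the
#' peak amplitude (defaults 0.9 to 0.1). Samples are weighted by
#' `(signal - diastolic)^2`, the first-order error-propagation weights for a
#' log transform under additive noise, which keeps the estimator nearly
#' unbiased when the tail samples are noisy. The fit is closed-form and
#' deterministic; it is invariant to adding a constant to the trace and
#' equivariant under time rescaling.
#'
#' @param trace A [uniform_trace()].
#' @param seg One segment from [detect_transients()].
#' @param fit_window Amplitude fractions (start, stop) bounding the fitted
#'   samples on the falling limb.
#' When consecutive transients overlap (slow decay relative to the beat
#' interval), the decay approaches the true diastolic asymptote while the
#' measurable pre-onset baseline sits above it by the carried-over tail, so
#' the default fit underestimates tau. `asymptote = "fit"` adds a
#' deterministic one-dimensional refinement that searches the offset
#' minimizing the weighted log-linear residual, recovering the asymptote
#' (and hence tau) exactly for noiseless superposed mono-exponentials.
#'
#' @param diastolic Baseline level; estimated from the pre-onset window when
#'   `NULL`. Samples at or below it are dropped with a warning.
#' @param baseline_ms Pre-onset baseline window width (ms) used when
#'   `diastolic` is `NULL`.
#' @param asymptote `"baseline"` (reference the pre-onset level) or `"fit"`
#'   (refine the decay asymptote; see Details).
#' @return Decay constant tau in ms (positive; a non-decreasing window is an
#'   error).
#' @export
fit_decay_tau <- function(trace, seg, fit_window = c(0.9, 0.1),
                          diastolic = NULL, baseline_ms = 30,
                          asymptote = c("baseline", "fit")) {
  asymptote <- match.arg(asymptote)
  stopifnot(inherits(trace, "uniform_trace"), fit_window[1] > fit_window[2])
  x <- trace$samples
  t <- trace_times(trace)
  if (is.null(diastolic)) {
    diastolic <- estimate_baseline(trace, seg, baseline_ms)$diastolic
  }
  amp <- x[seg$peak] - diastolic
  if (amp <= 0) stop("non-positive amplitude; cannot fit decay", call. = FALSE)
  idx <- seg$peak:seg$end
  # window bounded by the first crossing *times* of the two levels, so that
  # the inclusion of an individual sample does not depend on its own noise
  t_hi <- cross_time(x, t, seg$peak, seg$end,
                     diastolic + fit_window[1] * amp, rising = FALSE,
                     fallback = t[seg$peak])
  t_lo <- cross_time(x, t, seg$peak, seg$end,
                     diastolic + fit_window[2] * amp, rising = FALSE,
                     fallback = t[seg$end])
  sel <- idx[t[idx] >= t_hi & t[idx] <= t_lo]
  low <- sel[x[sel] <= diastolic]
  if (length(low)) {
    warning("fit window contains values at or below the baseline; shrinking",
            call. = FALSE)
    sel <- setdiff(sel, low)
  }
  if (length(sel) < 5L) {
    stop("fewer than 5 samples inside the decay fit window", call. = FALSE)
  }
  loglin_slope <- function(offset) {
    y <- x[sel] - offset
    fit <- stats::lm.wfit(cbind(1, t[sel]), log(y), w = y^2)
    structure(fit$coefficients[2],
              sse = sum(y^2 * fit$residuals^2))
  }
  if (asymptote == "fit") {
    lo <- diastolic - amp
    hi <- min(x[sel]) - 1e-9 * amp
    opt <- stats::optimize(function(d) attr(loglin_slope(d), "sse"),
                           interval = c(lo, hi), tol = 1e-10 * amp)
    diastolic <- opt$minimum
  }
  slope <- loglin_slope(diastolic)
  if (!is.finite(slope) || slope >= 0) {
    stop("decay fit window is not decreasing; tau undefined", call. = FALSE)
  }
  as.numeric(-1 / slope)
}

#' Average consecutive transients into one waveform
#'
#' Aligns the first `n` transients and returns their sample-wise mean as a
#' new trace (t = 0 at the alignment point). The default alignment fiducial
#' is the rising half-amplitude crossing ("upstroke"), which is robust to
#' sample-level noise; `align = "peak"` aligns on the per-transient argmax.
#' The averaged window spans from `pre_ms` before the fiducial to the
#' shortest segment end, so all averaged windows are complete.
#'
#' @param trace A [uniform_trace()].
#' @param segs Segments from [detect_transients()].
#' @param n Number of transients to average (default 10; fewer is an error
#'   naming the shortfall).
#' @param align `"upstroke"` or `"peak"`.
#' @param pre_ms Baseline context retained before the alignment point (ms).
#' @return A [uniform_trace()] of the averaged waveform.
#' @export
average_transients <- function(trace, segs, n = 10,
                               align = c("upstroke", "peak"), pre_ms = 30) {
  stopifnot(inherits(trace, "uniform_trace"))
  align <- match.arg(align)
  if (length(segs) < n) {
    stop(sprintf("only %d transient(s) available, %d requested for averaging",
                 length(segs), n), call. = FALSE)
  }
  segs <- segs[seq_len(n)]
  x <- trace$samples
  anchor <- vapply(segs, function(s) {
    if (align == "peak") return(s$peak)
    b0 <- x[s$start]
    half <- b0 + 0.5 * (x[s$peak] - b0)
    idx <- s$start:s$peak
    idx[min(which(x[idx] >= half))]
  }, integer(1))
  pre_n <- min(max(0L, round(pre_ms * trace$fs / 1000)), min(anchor) - 1L)
  post_n <- min(vapply(segs, function(s) s$end, integer(1)) - anchor)
  win <- vapply(seq_along(segs), function(j) {
    x[(anchor[j] - pre_n):(anchor[j] + post_n)]
  }, numeric(pre_n + post_n + 1L))
  avg <- if (is.matrix(win)) rowMeans(win) else win
  uniform_trace(avg, fs = trace$fs, t0 = -pre_n * 1000 / trace$fs,
                units = trace$units,
                label = sprintf("average of %d transients (%s-aligned)",
                                n, align))
}

#' Normalize per-group amplitudes to a reference group mean
#'
#' Expresses every value as a percentage of the reference group mean, so the
#' reference group averages 100%. Within-group ratios are preserved exactly.
#'
#' @param group_values Named list of numeric vectors, one per group.
#' @param reference_group Name of the reference group (non-empty, non-zero
#'   mean).
#' @return Named list of normalized values (%).
#' @export
normalize_amplitudes <- function(group_values, reference_group) {
  stopifnot(is.list(group_values), reference_group %in% names(group_values))
  ref <- group_values[[reference_group]]
  if (!length(ref)) stop("reference group is empty", call. = FALSE)
  m <- mean(ref)
  if (m == 0) stop("reference group mean is zero", call. = FALSE)
  lapply(group_values, function(v) 100 * v / m)
}

#' Indo-1 ratiometric calibration constants
#'
#' Bundles the constants of the ratio equation converting an Indo-1
#' fluorescence ratio R to free [Ca2+]:
#' \deqn{[Ca^{2+}] = K_d \beta (R - R_{min}) / (R_{max} - R)}
#' The defaults are typical in-situ values and are flagged as assumed; they
#' must be replaced by the calibration of the actual optical setup for
#' quantitative work.
#'
#' @param kd Dye dissociation constant in nM.
#' @param rmin Ratio at zero calcium.
#' @param rmax Ratio at saturating calcium.
#' @param beta Free/bound fluorescence ratio at the long wavelength.
#' @return An object of class `indo1_calibration`.
#' @export
indo1_calibration <- function(kd = 250, rmin = 0.3, rmax = 3, beta = 3) {
  stopifnot(kd > 0, beta > 0, rmin > 0, rmax > rmin)
  structure(list(kd = kd, rmin = rmin, rmax = rmax, beta = beta,
                 provenance = "assumed"),
            class = "indo1_calibration")
}

#' Convert an Indo-1 ratio to [Ca2+]
#'
#' @param r Fluorescence ratio(s) in `[rmin, rmax)`; `r = rmin` maps to
#'   0 nM.
#' @param calib An [indo1_calibration()].
#' @return Free [Ca2+] in nM (strictly increasing in `r`).
#' @seealso [ca_to_indo1()] for the algebraic inverse.
#' @export
indo1_to_ca <- function(r, calib = indo1_calibration()) {
  stopifnot(inherits(calib, "indo1_calibration"))
  if (any(r < calib$rmin | r >= calib$rmax)) {
    stop(sprintf("ratio outside the calibration range (%g, %g)",
                 calib$rmin, calib$rmax), call. = FALSE)
  }
  calib$kd * calib$beta * (r - calib$rmin) / (calib$rmax - r)
}

#' Convert [Ca2+] back to an Indo-1 ratio
#'
#' Algebraic inverse of [indo1_to_ca()].
#'
#' @param ca Free [Ca2+] in nM (>= 0).
#' @param calib An [indo1_calibration()].
#' @return Fluorescence ratio(s).
#' @export
ca_to_indo1 <- function(ca, calib = indo1_calibration()) {
  stopifnot(inherits(calib, "indo1_calibration"), all(ca >= 0))
  u <- ca / (calib$kd * calib$beta)
  (calib$rmin + u * calib$rmax) / (1 + u)
}

#' One-call calcium trace analysis
#'
#' Composes the full measurement chain used for a single recording: transient
#' detection, averaging of the first `n_average` transients (all of them when
#' fewer are available) and feature extraction on the averaged waveform, with
#' the transient frequency taken from the detection step.
#'
#' @param trace A [uniform_trace()].
#' @param n_average Number of consecutive transients to average.
#' @param min_prominence,min_separation_ms Passed to [detect_transients()].
#' @param recovery_frac,baseline_ms Passed to [transient_features()].
#' @param align Alignment fiducial for [average_transients()].
#' @return A list with elements `features` (one-row `ca_features`),
#'   `n_transients`, `segments` and `averaged` (the averaged waveform).
#' @export
analyze_calcium_trace <- function(trace, n_average = 10, min_prominence = 0.3,
                                  min_separation_ms = 100, recovery_frac = 0.9,
                                  baseline_ms = 30, align = "upstroke") {
  segs <- detect_transients(trace, min_prominence, min_separation_ms)
  if (!length(segs)) stop("no transients detected", call. = FALSE)
  n_use <- min(n_average, length(segs))
  avg <- average_transients(trace, segs, n = n_use, align = align,
                            pre_ms = baseline_ms)
  aseg <- list(start = 1L, peak = which.max(avg$samples),
               end = length(avg$samples))
  feats <- transient_features(avg, aseg, recovery_frac = recovery_frac,
                              baseline_ms = baseline_ms,
                              frequency = attr(segs, "frequency"))
  list(features = feats, n_transients = length(segs), segments = segs,
       averaged = avg)
}
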