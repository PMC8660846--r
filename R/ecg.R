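#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forwards and backwards
#' (`signal::filtfilt`), so the output is zero-phase and interval
#' measurements are not shifted; DC is removed by the pass band.
#'
#' @param trace A [uniform_trace()].
#' @param lo,hi Band edges in Hz (`lo < hi < fs/2`).
#' @param order Butterworth order of the underlying one-pass filter.
#' @return The filtered [uniform_trace()].
#' @export
ecg_bandpass <- function(trace, lo = 3, hi = 100, order = 2) {
  stopifnot(inherits(trace, "uniform_trace"))
  nyq <- trace$fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < lo < hi < fs/2 = %g",
                 lo, hi, nyq), call. = FALSE)
  }
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  y <- signal::filtfilt(bf, trace$samples)
  uniform_trace(y, fs = trace$fs, t0 = trace$t0, units = trace$units,
                label = paste0(trace$label, sprintf(" [%g-%g Hz]", lo, hi)))
}

#' Detect R peaks and heart rate
#'
#' R peaks are prominent maxima (prominence above `min_prominence` of the
#' trace range, separated by at least `min_rr_ms`); the heart rate is
#' `60 * (n - 1) / span(R times)`.
#'
#' Detection runs on a lightly smoothed copy of the trace (moving average of
#' `smooth_ms`, matched to the R-spike width) so single-sample noise
#' excursions cannot masquerade as beats; reported peak times are the
#' smoothed maxima.
#'
#' @param trace An ECG [uniform_trace()] (ideally band-passed).
#' @param min_prominence Fraction of the trace range.
#' @param min_rr_ms Refractory separation between R peaks.
#' @param smooth_ms Moving-average width for the detection copy (0 = none).
#' @return `list(times = <ms>, index = <sample indices>, hr = <bpm>)`.
#' @export
detect_beats <- function(trace, min_prominence = 0.4, min_rr_ms = 150,
                         smooth_ms = 5) {
  stopifnot(inherits(trace, "uniform_trace"))
  x <- trace$samples
  w <- round(smooth_ms * trace$fs / 1000)
  if (w > 1) x <- moving_average(x, w)
  rng <- diff(range(x))
  min_dist <- max(1L, round(min_rr_ms * trace$fs / 1000))
  peaks <- if (rng > 0) {
    find_prominent_peaks(x, min_prominence * rng, min_dist)
  } else integer(0)
  if (length(peaks) < 2L) {
    stop("fewer than 2 beats detected", call. = FALSE)
  }
  tt <- trace_times(trace)[peaks]
  list(times = tt, index = peaks,
       hr = 60 * (length(tt) - 1) / ((tt[length(tt)] - tt[1]) / 1000))
}

#' Ensemble-average ECG complexes
#'
#' Mean of R-aligned windows; windows truncated by the trace edges are
#' dropped. The window must fit between consecutive beats.
#'
#' @param trace An ECG [uniform_trace()].
#' @param r_times R-peak times (ms) from [detect_beats()].
#' @param window_ms Length-2 vector `(pre, post)`: window extent before and
#'   after each R peak (both positive).
#' @return A [uniform_trace()] of the averaged complex, `t = 0` at the R
#'   peak.
#' @export
ensemble_average <- function(trace, r_times, window_ms = c(250, 250)) {
  stopifnot(inherits(trace, "uniform_trace"), length(window_ms) == 2L,
            all(window_ms > 0))
  if (length(r_times) >= 2L && sum(window_ms) > min(diff(r_times))) {
    stop("averaging window exceeds the shortest inter-beat interval",
         call. = FALSE)
  }
  pre_n <- round(window_ms[1] * trace$fs / 1000)
  post_n <- round(window_ms[2] * trace$fs / 1000)
  centres <- trace_index_at(trace, r_times)
  ok <- centres - pre_n >= 1L & centres + post_n <= length(trace$samples)
  centres <- centres[ok]
  if (length(centres) < 2L) {
    stop("fewer than 2 complete windows to average", call. = FALSE)
  }
  win <- vapply(centres, function(c0) {
    trace$samples[(c0 - pre_n):(c0 + post_n)]
  }, numeric(pre_n + post_n + 1L))
  uniform_trace(rowMeans(win), fs = trace$fs,
                t0 = -pre_n * 1000 / trace$fs, units = trace$units,
                label = sprintf("ensemble average of %d complexes",
                                length(centres)))
}

#' Measure intervals and amplitudes on an averaged complex
#'
#' Conventions (the acquisition literature leaves the endpoints open, so
#' they are fixed here and documented): the R peak is the global maximum;
#' the P wave is the largest positive deflection ending `qrs_guard_ms`
#' before R; the isoelectric baseline is the median of the window before the
#' P wave; onsets are rising 10%-of-amplitude crossings (P onset on the P
#' upstroke, R onset on the R upstroke after the Q trough); PR = P onset to
#' R onset, PQ = P onset to the Q trough (the minimum between P and R).
#' Amplitudes are measured from the baseline. An undetectable P wave yields
#' `NA` intervals, not an error.
#'
#' @param avg Averaged complex from [ensemble_average()] (R peak at t = 0).
#' @param qrs_guard_ms Exclusion zone before the R peak when searching for P.
#' @param p_floor Minimum P amplitude, as a fraction of the R amplitude,
#'   below which P is flagged undetectable.
#' @param hr Optional heart rate (bpm) to carry into the result.
#' @return Object of class `ecg_stats`: `hr`, `pr`, `pq` (ms), `p_amp`,
#'   `r_amp` (signal units), `averaged_complex`.
#' @export
measure_complex <- function(avg, qrs_guard_ms = 25, p_floor = 0.05,
                            hr = NA_real_) {
  stopifnot(inherits(avg, "uniform_trace"))
  x <- avg$samples
  t <- trace_times(avg)
  i_r <- which.max(x)
  guard_n <- round(qrs_guard_ms * avg$fs / 1000)
  p_search_end <- i_r - guard_n
  out <- function(pr, pq, p_amp, baseline) {
    structure(list(hr = hr, pr = pr, pq = pq, p_amp = p_amp,
                   r_amp = x[i_r] - baseline, averaged_complex = avg),
              class = "ecg_stats")
  }
  if (p_search_end < 3L) return(out(NA_real_, NA_real_, NA_real_, 0))
  i_p <- which.max(x[seq_len(p_search_end)])
  # baseline: median of the segment well before the P wave
  base_end <- max(2L, i_p - round(3 * qrs_guard_ms * avg$fs / 1000 / 2))
  baseline <- stats::median(x[seq_len(base_end)])
  p_amp <- x[i_p] - baseline
  r_amp <- x[i_r] - baseline
  if (p_amp < p_floor * r_amp) return(out(NA_real_, NA_real_, NA_real_, baseline))

  # onsets found backwards from each peak (the last sub-level sample), so
  # noise crossings earlier in the window cannot masquerade as the onset
  p_onset <- onset_before_peak(x, t, i_p, baseline + 0.1 * p_amp)
  i_q <- i_p + which.min(x[i_p:i_r]) - 1L
  r_onset <- onset_before_peak(x, t, i_r, baseline + 0.1 * r_amp, from = i_q)
  s <- out(r_onset - p_onset, t[i_q] - p_onset, p_amp, baseline)
  s
}

# last sample below `level` before `peak` (searching back to `from`),
# linearly interpolated to the crossing instant
onset_before_peak <- function(x, t, peak, level, from = 1L) {
  below <- which(x[from:peak] < level)
  if (!length(below)) return(NA_real_)
  i <- from + max(below) - 1L
  if (i >= peak) return(NA_real_)
  x0 <- x[i]; x1 <- x[i + 1L]
  if (x1 == x0) return(t[i + 1L])
  t[i] + (level - x0) / (x1 - x0) * (t[i + 1L] - t[i])
}

#' @export
print.ecg_stats <- function(x, ...) {
  cat(sprintf(
    "ecg_stats: HR %.4g bpm, PR %.4g ms, PQ %.4g ms, P %.3g / R %.3g %s\n",
    x$hr, x$pr, x$pq, x$p_amp, x$r_amp, x$averaged_complex$units))
  invisible(x)
}

#' Full ECG analysis chain
#'
#' Band-pass filter, R-peak detection, ensemble averaging and complex
#' measurement in one call.
#'
#' @param trace Raw ECG [uniform_trace()].
#' @param band Pass band in Hz.
#' @param window_ms Averaging window `(pre, post)` around R; by default 45%
#'   of the shortest inter-beat interval on each side.
#' @return An `ecg_stats` object with `hr` filled from beat detection.
#' @export
analyze_ecg <- function(trace, band = c(3, 100), window_ms = NULL) {
  filt <- ecg_bandpass(trace, band[1], band[2])
  beats <- detect_beats(filt)
  if (is.null(window_ms)) {
    w <- 0.45 * min(diff(beats$times))
    window_ms <- c(w, w)
  }
  avg <- ensemble_average(filt, beats$times, window_ms)
  measure_complex(avg, hr = beats$hr)
}
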