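#' Split an AP recording into per-stimulus segments
#'
#' One segment per stimulus, running from the stimulus to the sample before
#' the next stimulus (or to the trace end for the last one).
#'
#' @param trace A membrane-potential [uniform_trace()] (mV).
#' @param stimuli A [stimulus_train()]; all times must lie inside the trace.
#' @return List of segments (`start`, `end` sample indices, `stim_time` ms).
#'   An empty stimulus train yields an empty list.
#' @export
segment_aps <- function(trace, stimuli) {
  stopifnot(inherits(trace, "uniform_trace"), inherits(stimuli, "stimulus_train"))
  times <- stimuli$times
  if (!length(times)) return(list())
  t_end <- trace$t0 + trace_duration(trace)
  if (any(times < trace$t0) || any(times > t_end)) {
    stop("stimulus times outside the trace span", call. = FALSE)
  }
  idx <- trace_index_at(trace, times)
  n <- length(trace$samples)
  lapply(seq_along(idx), function(k) {
    list(start = idx[k],
         end = if (k < length(idx)) idx[k + 1L] - 1L else n,
         stim_time = times[k])
  })
}

#' Action-potential features of one segment
#'
#' Measures the conventional AP parameters: resting membrane potential (mean
#' of the pre-upstroke window), maximal AP amplitude, plateau amplitude 50 ms
#' after the upstroke, APD20/50/90 (time from the maximal-upstroke-velocity
#' instant to the first crossing of `V_peak - x% * APA_max` on the falling
#' limb, linearly interpolated), maximal upstroke velocity, and the Phase-3
#' repolarization velocity (largest downward dV/dt between the 50% and 90%
#' repolarization crossings). Derivatives are central differences at the
#' recording rate. A repolarization level never reached before the segment
#' end yields `NA`, not an error.
#'
#' @param trace A membrane-potential [uniform_trace()] (mV).
#' @param seg One segment from [segment_aps()].
#' @param dvdt_threshold Upstroke detection threshold (V/s).
#' @return One-row data frame of class `ap_features`: `rmp`, `apa_max`,
#'   `apa_plat` (mV), `apd20`, `apd50`, `apd90` (ms), `dvdt_max`,
#'   `phase3_vmax` (V/s).
#' @export
ap_features <- function(trace, seg, dvdt_threshold = 10) {
  stopifnot(inherits(trace, "uniform_trace"))
  x <- trace$samples
  t <- trace_times(trace)
  idx <- seg$start:seg$end
  # central-difference derivative in V/s (mV/ms)
  dt <- 1000 / trace$fs
  dv <- c(NA, (x[idx][-(1:2)] - x[idx][seq_len(length(idx) - 2L)]) / (2 * dt), NA)
  i_thr <- which(dv > dvdt_threshold)[1]
  if (is.na(i_thr)) stop("no AP upstroke in segment", call. = FALSE)
  peak_rel <- which.max(x[idx])
  i_fid <- which.max(replace(dv, seq_along(dv) > peak_rel, NA)) # max dV/dt
  rmp <- mean(x[idx[seq_len(max(1L, i_thr - 1L))]])
  peak_v <- x[idx[peak_rel]]
  apa_max <- peak_v - rmp
  t_fid <- t[idx[i_fid]]

  i_plat <- idx[i_fid] + round(50 * trace$fs / 1000)
  apa_plat <- if (i_plat <= seg$end) x[i_plat] - rmp else NA_real_

  apd_at <- function(frac) {
    level <- peak_v - frac * apa_max
    tc <- cross_time(x, t, idx[peak_rel], seg$end, level, rising = FALSE,
                     fallback = NA_real_)
    tc - t_fid
  }
  apd20 <- apd_at(0.2); apd50 <- apd_at(0.5); apd90 <- apd_at(0.9)

  dvdt_max <- max(dv[seq_len(peak_rel)], na.rm = TRUE)

  phase3 <- NA_real_
  if (!is.na(apd50) && !is.na(apd90)) {
    j <- which(t[idx] >= t_fid + apd50 & t[idx] <= t_fid + apd90)
    if (length(j) >= 2L) phase3 <- abs(min(dv[j], na.rm = TRUE))
  }
  out <- data.frame(rmp = rmp, apa_max = apa_max, apa_plat = apa_plat,
                    apd20 = apd20, apd50 = apd50, apd90 = apd90,
                    dvdt_max = dvdt_max, phase3_vmax = phase3)
  class(out) <- c("ap_features", "data.frame")
  out
}

#' Average AP feature records
#'
#' Field-wise arithmetic mean over the first 10 records (the conventional
#' per-cell summary), or over all of them with a warning when fewer than 10
#' are supplied.
#'
#' @param features A data frame of [ap_features()] rows (or a list of
#'   one-row records, which is row-bound first).
#' @param n Number of consecutive records to average.
#' @return One-row `ap_features` data frame.
#' @export
average_ap_features <- function(features, n = 10) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- do.call(rbind, features)
  }
  if (!nrow(features)) stop("no AP feature records to average", call. = FALSE)
  if (nrow(features) < n) {
    warning(sprintf("only %d AP records available; averaging all of them",
                    nrow(features)), call. = FALSE)
    n <- nrow(features)
  }
  out <- as.data.frame(t(colMeans(features[seq_len(n), , drop = FALSE])))
  class(out) <- c("ap_features", "data.frame")
  out
}

#' APD90 alternans statistic
#'
#' Mean absolute APD90 difference between consecutive APs, the beat-to-beat
#' alternation measure used at fast pacing.
#'
#' @param apd90_series APD90 values of consecutive APs (ms, >= 2).
#' @return Object of class `alternans_result`: `mean_abs_diff` (ms),
#'   `n_pairs`, `per_pair_diffs`.
#' @export
apd_alternans <- function(apd90_series) {
  apd90_series <- as.numeric(apd90_series)
  if (length(apd90_series) < 2L) {
    stop("at least 2 APD90 values are needed for the alternans statistic",
         call. = FALSE)
  }
  d <- abs(diff(apd90_series))
  structure(list(mean_abs_diff = mean(d), n_pairs = length(d),
                 per_pair_diffs = d),
            class = "alternans_result")
}

#' @export
print.alternans_result <- function(x, ...) {
  cat(sprintf("APD90 alternans: mean |dAPD90| = %.3g ms over %d pairs\n",
              x$mean_abs_diff, x$n_pairs))
  invisible(x)
}

#' Detect delayed afterdepolarizations
#'
#' Scans a post-burst window for spontaneous depolarizations exceeding the
#' diastolic baseline by more than `threshold_mv` (> 1 mV by convention).
#' The baseline is the median of the `baseline_ms` preceding the window;
#' suprathreshold runs closer together than `merge_gap_ms` are merged into
#' one event.
#'
#' @param trace A membrane-potential [uniform_trace()] (mV).
#' @param window_ms Length-2 vector: start and end of the search window (ms,
#'   trace time base); must lie inside the trace. Place the window so that
#'   the preceding `baseline_ms` fall in the post-burst pause (after the last
#'   repolarization), not in the pacing burst itself — during fast pacing the
#'   membrane is depolarized for most of each cycle and would inflate the
#'   baseline.
#' @param threshold_mv Detection threshold above baseline (mV).
#' @param baseline_ms Width of the pre-window baseline (ms).
#' @param merge_gap_ms Events separated by less than this are merged.
#' @return Data frame with columns `time` (ms, at the event maximum) and
#'   `amplitude` (mV above baseline); zero rows when nothing crosses
#'   threshold.
#' @export
detect_dads <- function(trace, window_ms, threshold_mv = 1,
                        baseline_ms = 500, merge_gap_ms = 50) {
  stopifnot(inherits(trace, "uniform_trace"), length(window_ms) == 2L)
  t_end <- trace$t0 + trace_duration(trace)
  if (window_ms[2] > t_end || window_ms[1] < trace$t0) {
    stop("post-burst window outside the trace", call. = FALSE)
  }
  i0 <- trace_index_at(trace, window_ms[1])
  i1 <- trace_index_at(trace, window_ms[2])
  b0 <- trace_index_at(trace, window_ms[1] - baseline_ms)
  baseline <- stats::median(trace$samples[b0:max(b0, i0 - 1L)])
  x <- trace$samples[i0:i1]
  above <- x > baseline + threshold_mv
  none <- data.frame(time = numeric(0), amplitude = numeric(0))
  if (!any(above)) return(none)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than the refractory gap
  gap_n <- round(merge_gap_ms * trace$fs / 1000)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - merged[nrow(merged), 2] < gap_n) {
        merged[nrow(merged), 2] <- runs[k, 2]
      } else {
        merged <- rbind(merged, runs[k, , drop = FALSE])
      }
    }
  }
  t <- trace_times(trace)[i0:i1]
  ev <- apply(merged, 1, function(run) {
    seg <- run[1]:run[2]
    j <- seg[which.max(x[seg])]
    c(time = t[j], amplitude = x[j] - baseline)
  })
  as.data.frame(t(ev))
}

#' Partition steady-state K+ currents at a split voltage
#'
#' Quasi-steady-state currents at step potentials negative to `split_v` are
#' attributed to the inward-rectifier current (I_K1), positive to `split_v`
#' to the rapid delayed-rectifier current (I_Kr). Rows exactly at the split
#' voltage belong to neither partition.
#'
#' @param iv Data frame with columns `v_mV` and `i_pA` (steady-state
#'   current); voltages must be unique. Rows are sorted by voltage.
#' @param split_v Split potential (mV), -30 by convention.
#' @return `list(ik1 = <rows v < split_v>, ikr = <rows v > split_v>)`.
#' @export
partition_k_currents <- function(iv, split_v = -30) {
  stopifnot(is.data.frame(iv), all(c("v_mV", "i_pA") %in% names(iv)),
            nrow(iv) >= 1L)
  if (anyDuplicated(iv$v_mV)) {
    stop("I-V table has duplicate step voltages", call. = FALSE)
  }
  iv <- iv[order(iv$v_mV), , drop = FALSE]
  list(ik1 = iv[iv$v_mV < split_v, , drop = FALSE],
       ikr = iv[iv$v_mV > split_v, , drop = FALSE])
}

#' L-type calcium current from a P1 voltage step
#'
#' I_Ca,L is the difference between the peak (most negative) current during
#' the depolarizing step and the quasi-steady-state current, taken as the
#' mean over the last 10% of the step; the current density normalizes by the
#' cell capacitance.
#'
#' @param p1_trace A current [uniform_trace()] (pA) covering the P1 step.
#' @param cm Cell membrane capacitance (pF, > 0).
#' @param step_window_ms Optional length-2 window (ms) bounding the step;
#'   defaults to the whole trace.
#' @return `list(i_cal = <pA>, i_ss = <pA>, density = <pA/pF>)`.
#' @export
ical_two_pulse <- function(p1_trace, cm, step_window_ms = NULL) {
  stopifnot(inherits(p1_trace, "uniform_trace"))
  if (!is.numeric(cm) || cm <= 0) {
    stop("cell capacitance must be positive", call. = FALSE)
  }
  x <- p1_trace$samples
  if (!is.null(step_window_ms)) {
    i0 <- trace_index_at(p1_trace, step_window_ms[1])
    i1 <- trace_index_at(p1_trace, step_window_ms[2])
    x <- x[i0:i1]
  }
  n <- length(x)
  i_ss <- mean(x[(n - max(1L, floor(0.1 * n)) + 1L):n])
  i_cal <- min(x) - i_ss
  list(i_cal = i_cal, i_ss = i_ss, density = i_cal / cm)
}

#' Cell capacitance from the capacitive transient
#'
#' C_m is the decay time constant of the capacitive transient divided by the
#' series resistance; ms / MOhm gives nF, reported in pF.
#'
#' @param tau_cap Decay time constant of the capacitive transient (ms, > 0).
#' @param rs Series resistance (MOhm, > 0).
#' @return Object of class `cm_estimate`: `cm` (pF), `tau_cap`, `rs`.
#' @export
estimate_cm <- function(tau_cap, rs) {
  if (!is.numeric(tau_cap) || !is.numeric(rs) || tau_cap <= 0 || rs <= 0) {
    stop("tau_cap and rs must both be positive", call. = FALSE)
  }
  structure(list(cm = 1000 * tau_cap / rs, tau_cap = tau_cap, rs = rs),
            class = "cm_estimate")
}

#' @export
print.cm_estimate <- function(x, ...) {
  cat(sprintf("C_m = %.4g pF (tau %.4g ms / Rs %.4g MOhm)\n",
              x$cm, x$tau_cap, x$rs))
  invisible(x)
}
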