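#' Stimulus train
#'
#' Times of the pacing current pulses driving an action-potential recording.
#'
#' @param times Strictly increasing stimulus times in ms.
#' @param pacing_rate Pacing rate in Hz.
#' @return An object of class `stimulus_train`.
#' @export
stimulus_train <- function(times, pacing_rate) {
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0)) {
    stop("stimulus times must be strictly increasing", call. = FALSE)
  }
  stopifnot(pacing_rate > 0)
  structure(list(times = times, pacing_rate = as.numeric(pacing_rate)),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("stimulus_train: %d pulses at %g Hz\n",
              length(x$times), x$pacing_rate))
  invisible(x)
}

#' Simulate a paced action-potential train
#'
#' Generates a stylized ventricular AP waveform per stimulus: a smooth
#' (half-cosine) upstroke of `upstroke_ms`, a fast spike-to-plateau decay to
#' `rmp + plateau_frac * apa`, a sustained plateau, then a cosine
#' repolarization timed so that the 90%-repolarization crossing falls exactly
#' `apd90_even` (even-numbered beats) or `apd90_odd` (odd) after the
#' maximum-upstroke-velocity instant — the same fiducial the analysis uses.
#' This is a feature-controlled waveform, not a biophysical membrane model:
#' only the quantities the analyses measure (RMP, APA, plateau level, APD90,
#' alternans, DADs) are controlled; APD20/50 emerge from the shape.
#'
#' An optional delayed afterdepolarization is added after the last AP as a
#' Gaussian hump of the given amplitude.
#'
#' @param rmp Resting membrane potential (mV).
#' @param apa Action-potential amplitude (mV, > 0).
#' @param plateau_frac Plateau level as a fraction of `apa` above `rmp`.
#' @param apd90_even,apd90_odd APD90 of even/odd beats in ms (beat 1 is
#'   even-indexed 0); both must fit inside the pacing cycle. `apd90_odd`
#'   defaults to `apd90_even` (no alternans).
#' @param pacing Pacing rate (Hz).
#' @param n_aps Number of paced APs.
#' @param dad `NULL`, or `list(delay = <ms after the last stimulus>,
#'   amp = <mV>)`.
#' @param noise_sd Additive Gaussian noise sd (mV); requires `seed`.
#' @param fs Sampling rate (Hz), 40 kHz as for patch-clamp AP recordings.
#' @param seed Integer noise seed (bit-identical traces for equal seeds).
#' @param lead_in_ms Resting baseline before the first stimulus.
#' @param post_ms Recording continued after the last cycle (for DAD tests).
#' @param latency_ms Stimulus-to-upstroke latency.
#' @param upstroke_ms Upstroke duration.
#' @param spike_tau_ms Time constant of the spike-to-plateau decay.
#' @param plateau_end_frac Fraction of APD90 at which repolarization starts.
#' @return `list(trace = <uniform_trace, mV>, stimuli = <stimulus_train>)`,
#'   stimuli at t = 0, 1000/pacing, ...
#' @export
gen_ap_train <- function(rmp = -75, apa = 110, plateau_frac = 0.75,
                         apd90_even = 150, apd90_odd = NULL, pacing = 1,
                         n_aps = 10, dad = NULL, noise_sd = 0, fs = 40000,
                         seed = NULL, lead_in_ms = 20, post_ms = 1000,
                         latency_ms = 2, upstroke_ms = 1, spike_tau_ms = 5,
                         plateau_end_frac = 0.4) {
  if (is.null(apd90_odd)) apd90_odd <- apd90_even
  period <- 1000 / pacing
  stopifnot(apa > 0, n_aps >= 1, plateau_frac > 0.1, plateau_frac < 1)
  if (max(apd90_even, apd90_odd) >= period) {
    stop("APD90 must be shorter than the pacing cycle length", call. = FALSE)
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("`seed` is required when noise_sd > 0", call. = FALSE)
  }
  u <- upstroke_ms
  fid <- u / 2 # max-dV/dt instant of the half-cosine upstroke

  level_fun <- function(apd90) {
    t_r <- fid + plateau_end_frac * apd90
    if (t_r <= u) stop("APD90 too short for the upstroke", call. = FALSE)
    l_r <- plateau_frac +
      (1 - plateau_frac) * exp(-(t_r - u) / spike_tau_ms)
    theta <- acos(2 * 0.1 / l_r - 1)
    r_dur <- pi * (fid + apd90 - t_r) / theta
    if (latency_ms + t_r + r_dur >= period) {
      stop("overlapping APs: repolarization exceeds the pacing cycle",
           call. = FALSE)
    }
    function(s) {
      lev <- numeric(length(s))
      i1 <- s >= 0 & s <= u
      lev[i1] <- (1 - cos(pi * s[i1] / u)) / 2
      i2 <- s > u & s <= t_r
      lev[i2] <- plateau_frac +
        (1 - plateau_frac) * exp(-(s[i2] - u) / spike_tau_ms)
      i3 <- s > t_r & s <= t_r + r_dur
      lev[i3] <- l_r * (1 + cos(pi * (s[i3] - t_r) / r_dur)) / 2
      lev
    }
  }
  lev_even <- level_fun(apd90_even)
  lev_odd <- level_fun(apd90_odd)

  duration <- lead_in_ms + n_aps * period + post_ms
  n <- floor(duration * fs / 1000) + 1L
  t <- -lead_in_ms + (seq_len(n) - 1) * 1000 / fs
  v <- rep(rmp, n)
  stim_times <- (seq_len(n_aps) - 1) * period
  for (k in seq_len(n_aps)) {
    s <- t - stim_times[k] - latency_ms
    win <- s >= 0 & s < period
    f <- if ((k - 1) %% 2 == 0) lev_even else lev_odd
    v[win] <- rmp + apa * f(s[win])
  }
  if (!is.null(dad)) {
    stopifnot(is.numeric(dad$delay), is.numeric(dad$amp))
    centre <- stim_times[n_aps] + dad$delay
    v <- v + dad$amp * exp(-(t - centre)^2 / (2 * 25^2))
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    v <- v + stats::rnorm(n, sd = noise_sd)
  }
  list(
    trace = uniform_trace(v, fs = fs, t0 = -lead_in_ms, units = "mV",
                          label = sprintf("AP train, %g Hz pacing", pacing)),
    stimuli = stimulus_train(stim_times, pacing)
  )
}
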