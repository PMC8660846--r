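#' Simulate a fish surface ECG
#'
#' Stylized complexes per beat: a Gaussian P wave, a small Q trough, a narrow
#' R spike and a broad T wave. Wave onsets are taken as the rising
#' 10%-of-amplitude crossings (a Gaussian of sd s crosses 10% of its height
#' `s * sqrt(2 ln 10)` before its centre), and the P centre is placed so that
#' the P-onset to R-onset interval equals `pr` exactly. R peaks fall at
#' t = 0, 60000/hr, ...
#'
#' @param hr Heart rate (bpm).
#' @param pr PR interval in ms (P onset to R onset; must fit in the cycle).
#' @param p_amp,r_amp P- and R-wave amplitudes (arbitrary units).
#' @param fs Sampling rate (Hz).
#' @param noise_sd Additive Gaussian noise sd; requires `seed`.
#' @param seed Noise seed.
#' @param duration_s Recording length in seconds (R peaks at every full
#'   cycle that starts inside it).
#' @param t_amp,q_amp T-wave and Q-trough amplitudes.
#' @param sd_p,sd_r Gaussian widths of the P wave and R spike (ms).
#' @return A [uniform_trace()] with `t0` one cycle before the first R peak.
#' @export
gen_ecg <- function(hr, pr = 80, p_amp = 0.25, r_amp = 1, fs = 1000,
                    noise_sd = 0, seed = NULL, duration_s = 10,
                    t_amp = 0.3, q_amp = 0.12, sd_p = 10, sd_r = 4) {
  period <- 60000 / hr
  if (pr >= period) {
    stop("PR interval must be shorter than the cardiac cycle", call. = FALSE)
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("`seed` is required when noise_sd > 0", call. = FALSE)
  }
  k10 <- sqrt(2 * log(10))
  # P centre so that (cR - k10*sd_r) - (cP - k10*sd_p) = pr
  p_offset <- -pr - k10 * sd_r + k10 * sd_p # cP - cR
  lead_in <- period
  n <- floor((duration_s * 1000 + lead_in) * fs / 1000) + 1L
  t <- -lead_in + (seq_len(n) - 1) * 1000 / fs
  n_beats <- floor(duration_s * 1000 / period - 1e-9) + 1L
  r_centres <- (seq_len(n_beats) - 1) * period
  x <- numeric(n)
  gauss <- function(centre, amp, sd) amp * exp(-(t - centre)^2 / (2 * sd^2))
  for (cr in r_centres) {
    x <- x + gauss(cr, r_amp, sd_r) +
      gauss(cr + p_offset, p_amp, sd_p) -
      gauss(cr - 12, q_amp, 3) +
      gauss(cr + min(120, 0.35 * period), t_amp, 25)
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  uniform_trace(x, fs = fs, t0 = -lead_in, units = "arb",
                label = sprintf("ECG, %g bpm, PR %g ms", hr, pr))
}
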