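#' Simulate a Doppler beat table
#'
#' Per-beat ventricular-outflow peak velocities with controlled beat-to-beat
#' variability. In `"alternating"` mode beats take the values
#' `mean_pv * (1 +/- variation/2)`, so the downstream [pv_variation()]
#' statistic equals `variation` exactly (for an even number of beats); in
#' `"random"` mode beats get seeded Gaussian jitter with sd
#' `mean_pv * variation / 2`.
#'
#' @param mean_pv Mean peak velocity (mm/s, > 0).
#' @param variation Fractional beat-to-beat variation, in `[0, 2)`.
#' @param n_beats Number of beats (>= 6, the minimum for the per-fish
#'   variability statistic).
#' @param mode `"alternating"` or `"random"`.
#' @param seed Noise seed for random mode.
#' @param mean_vti Optional mean velocity-time integral (mm); when given, a
#'   constant `vti` column is included.
#' @return Data frame of class `beat_table` with columns `beat_index`, `pv`
#'   and optionally `vti`.
#' @export
gen_beat_series <- function(mean_pv, variation, n_beats,
                            mode = c("alternating", "random"), seed = NULL,
                            mean_vti = NULL) {
  mode <- match.arg(mode)
  stopifnot(mean_pv > 0)
  if (variation < 0 || variation >= 2) {
    stop("`variation` must lie in [0, 2)", call. = FALSE)
  }
  if (n_beats < 6) {
    stop("at least 6 beats are required per fish", call. = FALSE)
  }
  if (mode == "alternating") {
    pv <- mean_pv * (1 + rep_len(c(1, -1), n_beats) * variation / 2)
  } else {
    if (is.null(seed)) stop("`seed` is required in random mode", call. = FALSE)
    set.seed(as.integer(seed))
    pv <- mean_pv * (1 + stats::rnorm(n_beats, sd = variation / 2))
    if (any(pv <= 0)) pv <- pmax(pv, 0.01 * mean_pv)
  }
  out <- data.frame(beat_index = seq_len(n_beats), pv = pv)
  if (!is.null(mean_vti)) out$vti <- rep(mean_vti, n_beats)
  class(out) <- c("beat_table", "data.frame")
  out
}
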