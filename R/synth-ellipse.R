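#' Per-frame ellipse axis series
#'
#' @param major,minor Major/minor axis per frame (um; `major >= minor > 0`).
#' @param fs Frame rate (Hz).
#' @return Data frame of class `ellipse_series` with columns `frame`,
#'   `time_ms`, `major`, `minor` and attribute `fs`.
#' @export
ellipse_series <- function(major, minor, fs) {
  stopifnot(length(major) == length(minor), fs > 0, all(minor > 0),
            all(major >= minor))
  out <- data.frame(frame = seq_along(major),
                    time_ms = (seq_along(major) - 1) * 1000 / fs,
                    major = major, minor = minor)
  attr(out, "fs") <- fs
  class(out) <- c("ellipse_series", "data.frame")
  out
}

#' Simulate a beating-ventricle ellipse series
#'
#' Axes interpolate sinusoidally between the end-diastolic and end-systolic
#' extremes, starting at end-diastole; with a pure sinusoid, contraction and
#' relaxation each take half a cycle.
#'
#' @param ed_major,ed_minor End-diastolic axes (um).
#' @param es_major,es_minor End-systolic axes (um; each `<=` its diastolic
#'   counterpart, and the systolic volume must not exceed the diastolic one).
#' @param hr Heart rate (bpm).
#' @param fps Frame rate (Hz); at least 8 frames per cycle are required.
#' @param n_cycles Number of cardiac cycles.
#' @return An [ellipse_series()].
#' @export
gen_ellipse_series <- function(ed_major, ed_minor, es_major, es_minor,
                               hr, fps, n_cycles) {
  stopifnot(ed_major > 0, ed_minor > 0, es_major > 0, es_minor > 0,
            hr > 0, n_cycles >= 1)
  edv <- ellipse_area_volume(ed_major, ed_minor)$volume
  esv <- ellipse_area_volume(es_major, es_minor)$volume
  if (esv > edv) {
    stop("end-systolic volume exceeds end-diastolic volume", call. = FALSE)
  }
  if (ed_major < es_major || ed_minor < es_minor) {
    stop("end-diastolic axes must not be smaller than end-systolic axes",
         call. = FALSE)
  }
  frames_per_cycle <- fps * 60 / hr
  if (frames_per_cycle < 8) {
    stop("fewer than 8 frames per cardiac cycle; increase fps", call. = FALSE)
  }
  n <- floor(n_cycles * frames_per_cycle) + 1L
  phase <- 2 * pi * (hr / 60) * (seq_len(n) - 1) / fps
  w <- (1 + cos(phase)) / 2 # 1 at end-diastole, 0 at end-systole
  ellipse_series(es_major + (ed_major - es_major) * w,
                 es_minor + (ed_minor - es_minor) * w, fs = fps)
}

#' Render an ellipse series as binary masks (optionally a TIFF movie)
#'
#' One filled ellipse per frame on a black background, 8-bit grayscale when
#' written to a multi-page TIFF.
#'
#' @param series An [ellipse_series()].
#' @param um_per_px Spatial scale (um per pixel).
#' @param pad_px Margin around the largest ellipse.
#' @param path Optional output TIFF path.
#' @return Invisibly, the list of logical mask matrices (rows = y).
#' @export
render_ellipse_movie <- function(series, um_per_px = 1, pad_px = 6,
                                 path = NULL) {
  stopifnot(inherits(series, "ellipse_series"))
  a_px <- series$major / (2 * um_per_px) # semi-axes in px
  b_px <- series$minor / (2 * um_per_px)
  w <- 2 * (ceiling(max(a_px)) + pad_px) + 1L
  h <- 2 * (ceiling(max(b_px)) + pad_px) + 1L
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  masks <- lapply(seq_len(nrow(series)), function(i) {
    ((xs - cx) / a_px[i])^2 + ((ys - cy) / b_px[i])^2 <= 1
  })
  if (!is.null(path)) {
    tiff::writeTIFF(lapply(masks, function(m) m * 1), path,
                    bits.per.sample = 8L)
  }
  invisible(masks)
}

#' Read a mask movie from a multi-page TIFF
#'
#' @param path TIFF path written by [render_ellipse_movie()] (or any
#'   grayscale movie of one bright object per frame).
#' @param threshold Foreground threshold on the [0, 1] intensity scale.
#' @return List of logical mask matrices.
#' @export
read_ellipse_movie <- function(path, threshold = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p > threshold
  })
}
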