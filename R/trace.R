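#' Uniformly sampled signal trace
#'
#' The common carrier for all recordings handled by the package: fluorescence
#' or ratiometric calcium signals, membrane potential (mV), membrane current
#' (pA) and ECG (arbitrary units). Time is kept in milliseconds and the
#' sampling rate in Hz.
#'
#' @param samples Numeric vector of signal values (at least 2, no missing
#'   values).
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in ms. Generators place the first event
#'   at t = 0 and use a negative `t0` for the baseline lead-in.
#' @param units Unit label for the samples (e.g. `"arb"`, `"mV"`, `"pA"`,
#'   `"nM"`).
#' @param label Free-text description of the recording.
#'
#' @return An object of class `uniform_trace`: a list with elements
#'   `samples`, `fs`, `t0`, `units`, `label`.
#' @examples
#' tr <- uniform_trace(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' print(tr)
#' head(trace_times(tr))
#' @export
uniform_trace <- function(samples, fs, t0 = 0, units = "arb", label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a uniform_trace needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(samples)) {
    stop("a uniform_trace must not contain missing values", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
         units = as.character(units), label = as.character(label)),
    class = "uniform_trace"
  )
}

#' Sample times of a trace
#'
#' @param trace A [uniform_trace()].
#' @return Numeric vector of sample times in ms.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "uniform_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) * 1000 / trace$fs
}

#' Trace duration in ms
#' @param trace A [uniform_trace()].
#' @return Duration spanned by the samples, in ms.
#' @export
trace_duration <- function(trace) {
  (length(trace$samples) - 1) * 1000 / trace$fs
}

#' Index of the sample nearest to a time point
#' @param trace A [uniform_trace()].
#' @param t_ms Time in ms.
#' @return Integer sample index (clamped to the trace).
#' @export
trace_index_at <- function(trace, t_ms) {
  i <- round((t_ms - trace$t0) * trace$fs / 1000) + 1
  as.integer(pmin(pmax(i, 1L), length(trace$samples)))
}

#' @export
print.uniform_trace <- function(x, ...) {
  cat(sprintf("uniform_trace: %d samples @ %g Hz (%.1f ms), units = %s\n",
              length(x$samples), x$fs, trace_duration(x), x$units))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  cat(sprintf("  range: [%.4g, %.4g], t0 = %g ms\n",
              min(x$samples), max(x$samples), x$t0))
  invisible(x)
}

#' @export
plot.uniform_trace <- function(x, ..., xlab = "time (ms)", ylab = NULL,
                               type = "l") {
  if (is.null(ylab)) ylab <- x$units
  graphics::plot(trace_times(x), x$samples, type = type,
                 xlab = xlab, ylab = ylab, main = x$label, ...)
  invisible(x)
}

#' @export
as.data.frame.uniform_trace <- function(x, ...) {
  data.frame(time_ms = trace_times(x), value = x$samples)
}

#' Write a trace to delimited text
#'
#' Two-column CSV (`time_ms,value`) preceded by a `#`-prefixed metadata line
#' recording sampling rate, units, start time and label, so that
#' [read_trace_csv()] restores an identical object.
#'
#' @param trace A [uniform_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "uniform_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g t0=%.17g units=%s label=%s",
                     trace$fs, trace$t0, trace$units, trace$label), con)
  utils::write.table(as.data.frame(trace), con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param path File path.
#' @return A [uniform_trace()].
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) {
    stop("not a trace CSV: missing '#' metadata header", call. = FALSE)
  }
  meta <- sub("^#\\s*", "", header)
  get <- function(key, default = "") {
    m <- regmatches(meta, regexec(paste0(key, "=(\\S*)"), meta))[[1]]
    if (length(m) < 2) default else m[2]
  }
  fs <- as.numeric(get("fs"))
  t0 <- as.numeric(get("t0", "0"))
  units <- get("units", "arb")
  # label may contain spaces: everything after 'label='
  label <- sub(".*label=", "", meta)
  df <- utils::read.csv(path, comment.char = "#")
  uniform_trace(df$value, fs = fs, t0 = t0, units = units, label = label)
}
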