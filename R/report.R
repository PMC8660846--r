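#' Group mean and standard error
#'
#' The summary used throughout the figures: mean +/- SEM with the sample
#' standard deviation (n - 1 denominator); a single value has SEM 0.
#'
#' @param values Numeric vector (non-empty).
#' @param group Optional group label.
#' @return One-row data frame: `group`, `n`, `mean`, `sem`.
#' @export
mean_sem <- function(values, group = NA_character_) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty value vector", call. = FALSE)
  s <- if (length(values) == 1L) 0 else stats::sd(values)
  data.frame(group = group, n = length(values), mean = mean(values),
             sem = s / sqrt(length(values)))
}

#' Percent change relative to a reference
#'
#' `100 * (reference - value) / reference`: a reduction is positive, an
#' increase negative.
#'
#' @param reference Reference value (non-zero).
#' @param value Comparison value.
#' @return Percent change.
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("reference must be non-zero", call. = FALSE)
  100 * (reference - value) / reference
}

#' qPCR fold change by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,ctrl - Ct_ref,ctrl)`
#' and `FC = 2^-ddCt`.
#'
#' @param ct_target_test,ct_ref_test Target/reference-gene Ct in the test
#'   sample.
#' @param ct_target_ctrl,ct_ref_ctrl Target/reference-gene Ct in the control
#'   sample.
#' @return `list(ddct = <cycles>, fold_change = <x-fold>)`.
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(cts))) stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  list(ddct = ddct, fold_change = 2^(-ddct))
}

#' Pair baseline and treated feature tables
#'
#' Inner-joins two per-subject feature tables on `key` and computes
#' `delta = treated - baseline` for every shared numeric feature. Subjects
#' present in only one table are dropped with a warning that lists them.
#'
#' @param baseline,treated Data frames with a shared key column and numeric
#'   feature columns.
#' @param key Name of the subject identifier column.
#' @return Data frame with, per shared feature `f`, columns `f_baseline`,
#'   `f_treated`, `f_delta`.
#' @export
paired_table <- function(baseline, treated, key = "subject") {
  stopifnot(key %in% names(baseline), key %in% names(treated))
  unmatched <- c(setdiff(baseline[[key]], treated[[key]]),
                 setdiff(treated[[key]], baseline[[key]]))
  if (length(unmatched)) {
    warning("dropping unmatched subject(s): ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  feats <- setdiff(intersect(names(baseline), names(treated)), key)
  feats <- feats[vapply(feats, function(f) is.numeric(baseline[[f]]),
                        logical(1))]
  m <- merge(baseline[, c(key, feats), drop = FALSE],
             treated[, c(key, feats), drop = FALSE],
             by = key, suffixes = c("_baseline", "_treated"))
  for (f in feats) {
    m[[paste0(f, "_delta")]] <-
      m[[paste0(f, "_treated")]] - m[[paste0(f, "_baseline")]]
  }
  m[order(m[[key]]), , drop = FALSE]
}

#' Write / read a beat table
#'
#' Plain CSV with a `#` metadata line so the table round-trips through
#' [read_beat_table()].
#'
#' @param beats A [gen_beat_series()] table.
#' @param path File path.
#' @return `path` invisibly (writer); a `beat_table` data frame (reader).
#' @export
write_beat_table <- function(beats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# beat_table pv=mm/s vti=mm", con)
  utils::write.table(beats, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beat_table
#' @export
read_beat_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  class(df) <- c("beat_table", "data.frame")
  df
}
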