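#' Named simulation presets
#'
#' Parameter bundles for the synthetic-data generators, one per simulated
#' condition. Embryonic presets carry GCaMP6f fluorescence parameters on the
#' normalized-percent scale (amplitude and decay constant pinned to published
#' wild-type / R14del group means); adult presets carry Indo-1 calibrated
#' [Ca2+] parameters in nM. Each field records its provenance (`"published"` for
#' a published group mean, `"assumed"` for a value chosen here) in the
#' `provenance` attribute; the packaged JSON file additionally carries a note
#' per field.
#'
#' @param name One of `"wt_embryo"`, `"r14del_embryo"`, `"r14del_istaroxime"`,
#'   `"wt_adult"`, `"r14del_adult"`.
#' @return An object of class `generator_preset`: a list with fields `name`,
#'   `diastolic_level`, `amplitude`, `tau_rise`, `tau_decay` (ms),
#'   `beat_rate` (Hz), `noise_sd`, `upstroke_mode` and `units`, with
#'   attributes `provenance` and `notes` (named character vectors).
#' @examples
#' p <- make_preset("wt_embryo")
#' p$tau_decay # 105.74 ms
#' attr(p, "provenance")[["tau_decay"]] # "published"
#' @export
make_preset <- function(name) {
  presets <- .load_preset_file()
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; available: %s",
                 as.character(name)[1],
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  entry <- presets[[name]]
  fields <- entry$fields
  value_of <- function(f) fields[[f]]$value
  p <- list(
    name = name,
    diastolic_level = as.numeric(value_of("diastolic_level")),
    amplitude = as.numeric(value_of("amplitude")),
    tau_rise = as.numeric(value_of("tau_rise")),
    tau_decay = as.numeric(value_of("tau_decay")),
    beat_rate = as.numeric(value_of("beat_rate")),
    noise_sd = as.numeric(value_of("noise_sd")),
    upstroke_mode = as.character(value_of("upstroke_mode")),
    units = entry$units
  )
  attr(p, "provenance") <- vapply(fields, function(f) f$provenance, character(1))
  attr(p, "notes") <- vapply(fields, function(f) f$note, character(1))
  attr(p, "description") <- entry$description
  class(p) <- "generator_preset"
  validate_preset(p)
  p
}

#' List available preset names
#' @return Character vector of preset names.
#' @export
list_presets <- function() names(.load_preset_file())

.load_preset_file <- function() {
  path <- system.file("extdata", "presets.json", package = "cardiotrace")
  if (!nzchar(path)) stop("packaged preset file not found", call. = FALSE)
  jsonlite::read_json(path)
}

validate_preset <- function(p) {
  stopifnot(
    p$tau_decay > 0, p$amplitude > 0, p$beat_rate > 0, p$tau_rise >= 0,
    p$noise_sd >= 0
  )
  if ((p$upstroke_mode == "instantaneous") != (p$tau_rise == 0)) {
    stop("upstroke_mode 'instantaneous' requires tau_rise = 0 (and vice versa)",
         call. = FALSE)
  }
  if (!p$upstroke_mode %in% c("instantaneous", "exponential")) {
    stop("upstroke_mode must be 'instantaneous' or 'exponential'", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.generator_preset <- function(x, ...) {
  cat(sprintf("generator_preset '%s' (units: %s)\n", x$name, x$units))
  prov <- attr(x, "provenance")
  for (f in c("diastolic_level", "amplitude", "tau_rise", "tau_decay",
              "beat_rate", "noise_sd", "upstroke_mode")) {
    cat(sprintf("  %-16s %-14s [%s]\n", f, format(x[[f]]), prov[[f]]))
  }
  invisible(x)
}

# Copy a preset with some fields replaced (keeps the coupling between
# upstroke_mode and tau_rise consistent).
#' Modify a preset
#'
#' Returns a copy of `preset` with the named fields replaced. Changed fields
#' are re-marked as `"modified"` in the provenance attribute, and the
#' upstroke-mode/tau_rise coupling is restored automatically.
#'
#' @param preset A [make_preset()] object.
#' @param ... Named fields to replace (e.g. `tau_rise = 20`).
#' @return A `generator_preset`.
#' @export
preset_with <- function(preset, ...) {
  stopifnot(inherits(preset, "generator_preset"))
  changes <- list(...)
  bad <- setdiff(names(changes), names(preset))
  if (length(bad)) {
    stop("unknown preset fields: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  prov <- attr(preset, "provenance")
  for (nm in names(changes)) {
    preset[[nm]] <- changes[[nm]]
    if (nm %in% names(prov)) prov[[nm]] <- "modified"
  }
  if (!"upstroke_mode" %in% names(changes)) {
    preset$upstroke_mode <- if (preset$tau_rise == 0) "instantaneous" else "exponential"
  }
  attr(preset, "provenance") <- prov
  validate_preset(preset)
  preset
}
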