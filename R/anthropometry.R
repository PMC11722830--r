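#' Segment lengths of the planar lifting chain
#'
#' Bundles the five link lengths of the sagittal-plane body chain used by
#' the hand-location model: forearm, upper arm, back (hip to shoulder),
#' thigh (hip to knee) and calf (ankle to knee), all in metres.
#'
#' All lengths must be strictly positive and below 1.5 m; the upper bound
#' catches unit mistakes (centimetres passed as metres) -- no adult human
#' segment approaches 1.5 m.
#'
#' @param forearm,upper_arm,back,thigh,calf segment lengths in metres.
#' @return A named numeric vector of class `"segment_lengths"` with
#'   elements `forearm`, `upper_arm`, `back`, `thigh`, `calf`.
#' @examples
#' segment_lengths(0.25, 0.30, 0.50, 0.45, 0.43)
#' @export
segment_lengths <- function(forearm, upper_arm, back, thigh, calf) {
  x <- c(forearm = forearm, upper_arm = upper_arm, back = back,
         thigh = thigh, calf = calf)
  validate_segment_lengths(x)
  structure(x, class = "segment_lengths")
}

validate_segment_lengths <- function(x) {
  if (!is.numeric(x) || length(x) != 5L || !all(names(x) == SEGMENT_NAMES))
    stop_invalid("segment lengths must be the five named values ",
                 paste(SEGMENT_NAMES, collapse = ", "))
  if (any(!is.finite(x)))
    stop_invalid("segment lengths must be finite")
  if (any(x <= 0))
    stop_invalid("segment lengths must be strictly positive; got ",
                 paste0(names(x)[x <= 0], " = ", x[x <= 0], collapse = ", "))
  if (any(x >= 1.5))
    stop_invalid("segment length over the 1.5 m sanity bound (units?): ",
                 paste0(names(x)[x >= 1.5], " = ", x[x >= 1.5], collapse = ", "))
  invisible(x)
}

#' @export
print.segment_lengths <- function(x, ...) {
  cat("Segment lengths (m):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Segment-to-forearm length ratios
#'
#' Dimensionless ratios of each segment length to the forearm length, used
#' by the forearm-ratio anthropometric model.  The forearm ratio is fixed
#' at 1 by definition.
#'
#' The defaults follow the classical Drillis--Contini stature proportions
#' (forearm 0.146, upper arm 0.186, trunk 0.288, thigh 0.245, calf 0.246
#' of stature), re-expressed relative to the forearm.  They are plain
#' arguments -- substitute population-specific values where available.
#'
#' @param upper_arm,back,thigh,calf ratios of each segment length to the
#'   forearm length (dimensionless, strictly positive).
#' @return A named numeric vector of class `"segment_ratios"`.
#' @examples
#' default_segment_ratios()
#' @export
segment_ratios <- function(upper_arm = 1.27, back = 1.97,
                           thigh = 1.68, calf = 1.69) {
  x <- c(forearm = 1, upper_arm = upper_arm, back = back,
         thigh = thigh, calf = calf)
  if (any(!is.finite(x)) || any(x <= 0))
    stop_invalid("segment ratios must be finite and strictly positive")
  structure(x, class = "segment_ratios")
}

#' @rdname segment_ratios
#' @export
default_segment_ratios <- function() segment_ratios()

#' Drillis--Contini segment-length fractions of stature
#'
#' Classical population mean fractions of standing stature for the five
#' chain segments; the synthetic-subject generator draws individual
#' lengths around these.
#'
#' @return Named numeric vector of stature fractions.
#' @export
default_segment_fractions <- function() {
  c(forearm = 0.146, upper_arm = 0.186, back = 0.288,
    thigh = 0.245, calf = 0.246)
}

#' Build segment lengths from a single forearm measurement
#'
#' The ratio model: every segment length is the measured forearm length
#' scaled by a population segment-to-forearm ratio, so the wearable system
#' needs only one tape measurement per subject.
#'
#' @param forearm_length forearm length in metres (> 0).
#' @param ratios a [segment_ratios()] object.
#' @return A [segment_lengths()] object; the forearm entry equals the
#'   input exactly.
#' @examples
#' segments_from_forearm(0.25)
#' @export
segments_from_forearm <- function(forearm_length,
                                  ratios = default_segment_ratios()) {
  if (!is.numeric(forearm_length) || length(forearm_length) != 1L ||
      !is.finite(forearm_length) || forearm_length <= 0)
    stop_invalid("forearm_length must be a single positive finite number")
  if (!inherits(ratios, "segment_ratios"))
    ratios <- do.call(segment_ratios, as.list(ratios[setdiff(names(ratios), "forearm")]))
  x <- forearm_length * unclass(ratios)
  segment_lengths(x[["forearm"]], x[["upper_arm"]], x[["back"]],
                  x[["thigh"]], x[["calf"]])
}

#' Build segment lengths from direct measurements
#'
#' The ratio + length model's anthropometry: all five segments are
#' individually measured.  Values pass through unchanged after validation.
#'
#' @inheritParams segment_lengths
#' @return A [segment_lengths()] object equal to the inputs.
#' @export
segments_from_measurements <- function(forearm, upper_arm, back, thigh, calf) {
  segment_lengths(forearm, upper_arm, back, thigh, calf)
}

#' Read anthropometry from a JSON or YAML config file
#'
#' Two schemas are accepted: either the five segment lengths
#' (`forearm`, `upper_arm`, `back`, `thigh`, `calf`, metres), or
#' `forearm` plus a `ratios` table (segment-to-forearm ratios) for the
#' ratio model.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A [segment_lengths()] object.
#' @export
read_anthropometry <- function(path) {
  cfg <- read_config_file(path)
  have <- intersect(SEGMENT_NAMES, names(cfg))
  if (length(have) == 5L) {
    segments_from_measurements(cfg$forearm, cfg$upper_arm, cfg$back,
                               cfg$thigh, cfg$calf)
  } else if ("forearm" %in% names(cfg)) {
    ratios <- if (is.null(cfg$ratios)) default_segment_ratios() else
      segment_ratios(upper_arm = cfg$ratios$upper_arm, back = cfg$ratios$back,
                     thigh = cfg$ratios$thigh, calf = cfg$ratios$calf)
    segments_from_forearm(cfg$forearm, ratios)
  } else {
    stop_invalid("anthropometry config needs either all five segment ",
                 "lengths or a forearm length (plus optional ratios)")
  }
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop_invalid("unsupported config extension '.", ext,
                 "' (use .json, .yaml or .yml)")
  }
}
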