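# Registry of pluggable central-pressure estimators. An estimator is a
# function(calibrated_pulse, brachial, ...) returning list(csbp, cmap, cdbp).
.estimators <- new.env(parent = emptyenv())

#' Register a central-pressure estimator
#'
#' Estimators receive the calibrated ensemble pulse (numeric vector, mmHg,
#' time-average equal to brachial MAP and minimum equal to brachial DBP) and
#' the `brachial_estimate`, and must return a list with `csbp`, `cmap`,
#' `cdbp`. This is the plug-in point at which a manufacturer's transfer
#' function would be attached; the shipped default is an openly simple
#' surrogate, not a reconstruction of any proprietary algorithm.
#'
#' @param id Estimator name.
#' @param fn Function `(calibrated_pulse, brachial, ...) -> list(csbp, cmap,
#'   cdbp)`.
#' @export
register_estimator <- function(id, fn) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  assign(id, fn, envir = .estimators)
  invisible(id)
}

#' @rdname register_estimator
#' @export
list_estimators <- function() sort(ls(.estimators))

get_estimator <- function(id) {
  if (!exists(id, envir = .estimators, inherits = FALSE))
    stop("unknown estimator '", id, "'; registered: ",
         paste(list_estimators(), collapse = ", "), call. = FALSE)
  get(id, envir = .estimators, inherits = FALSE)
}

# Default surrogate: central DBP and MAP equal the calibrated brachial
# values; central SBP sits a fraction alpha of the way from MAP to the
# calibrated pulse peak (alpha = 1 reproduces the peak itself).
surrogate_estimator <- function(calibrated_pulse, brachial, alpha = 0.8) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  list(csbp = brachial$map + alpha * (max(calibrated_pulse) - brachial$map),
       cmap = brachial$map,
       cdbp = brachial$dbp)
}

register_estimator("ratio_surrogate", surrogate_estimator)
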