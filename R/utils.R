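# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not perturb
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Convert a Gaussian FWHM to its standard deviation
#'
#' FWHM = 2 * sqrt(2 * ln 2) * sigma.
#'
#' @param fwhm Full width at half maximum (same units as the result).
#' @return Standard deviation.
#' @export
fwhm_to_sigma <- function(fwhm) {
  stopifnot(is.numeric(fwhm), all(fwhm >= 0))
  fwhm / (2 * sqrt(2 * log(2)))
}

# Round half away from zero (base round() rounds half to even; printed
# whole-number percentages follow the conventional rule).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
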