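#' TL-BHE parameter pair
#'
#' Bundles the rate parameter \eqn{\pi > 0} (units 1/time) and the shape
#' parameter \eqn{\alpha > 0} (dimensionless) of the Topp-Leone
#' Burr-Hatke exponential distribution. All distribution and estimation
#' functions accept either a `tlbhe_params` object or the two parameters
#' separately.
#'
#' @param rate positive rate parameter \eqn{\pi}.
#' @param shape positive shape parameter \eqn{\alpha}.
#' @return an object of class `tlbhe_params`: a named list with elements
#'   `rate` and `shape`.
#' @examples
#' p <- tlbhe_params(rate = 1, shape = 1.5)
#' dtlbhe(1, p)
#' @export
tlbhe_params <- function(rate, shape) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive finite number")
  if (!is.numeric(shape) || length(shape) != 1 || !is.finite(shape) || shape <= 0)
    stop("'shape' must be a single positive finite number")
  structure(list(rate = as.numeric(rate), shape = as.numeric(shape)),
            class = "tlbhe_params")
}

#' @export
print.tlbhe_params <- function(x, ...) {
  cat(sprintf("TL-BHE parameters: rate (pi) = %g, shape (alpha) = %g\n",
              x$rate, x$shape))
  invisible(x)
}

# normalise (params-object | rate, shape) argument styles
resolve_params <- function(rate, shape) {
  if (inherits(rate, "tlbhe_params")) {
    if (!missing(shape) && !is.null(shape))
      stop("supply either a tlbhe_params object or rate and shape, not both")
    return(rate)
  }
  tlbhe_params(rate, shape)
}
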