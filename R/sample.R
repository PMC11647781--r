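#' Lifetime sample container
#'
#' Wraps a vector of positive lifetimes with a label. Values are stored
#' sorted ascending; the original input order is retained in the
#' `order` attribute-like field so provenance is not lost.
#'
#' @param values numeric vector of strictly positive lifetimes.
#' @param name optional text label.
#' @return object of class `tlbhe_sample` with fields `values` (sorted),
#'   `order` (permutation recovering the input order), `name`, `n`.
#' @examples
#' s <- tlbhe_sample(c(2.3, 0.7, 1.1), name = "toy")
#' s$n
#' @export
tlbhe_sample <- function(values, name = "sample") {
  values <- as.numeric(values)
  if (length(values) < 1) stop("empty sample")
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("sample values must be positive and finite; offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  ord <- order(values)
  structure(list(values = values[ord], order = order(ord),
                 name = name, n = length(values)),
            class = "tlbhe_sample")
}

#' @export
print.tlbhe_sample <- function(x, ...) {
  cat(sprintf("TL-BHE sample '%s': n = %d, range [%g, %g], mean %.4g\n",
              x$name, x$n, min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# accept tlbhe_sample or bare numeric, return sorted positive values
sample_values <- function(x) {
  if (inherits(x, "tlbhe_sample")) return(x$values)
  tlbhe_sample(x)$values
}
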