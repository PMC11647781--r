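#' Principal branch of the Lambert W function
#'
#' Solves \eqn{w e^w = z} for \eqn{w \ge -1} (the principal branch
#' \eqn{W_0}), vectorised over `z`. Used internally to invert the TL-BHE
#' cdf, where the argument is always \eqn{\ge e}, but the implementation
#' is valid on the whole principal domain \eqn{z \ge -1/e}.
#'
#' @param z numeric vector, each element \eqn{\ge -1/e}.
#' @return numeric vector of the same length with \eqn{W_0(z)}.
#' @examples
#' lambert_w0(exp(1))   # 1
#' lambert_w0(0)        # 0
#' @export
lambert_w0 <- function(z) {
  out <- numeric(length(z))
  out[is.na(z)] <- NA_real_
  if (any(z < -exp(-1) - 1e-12, na.rm = TRUE)) {
    stop("lambert_w0: argument below -1/e is outside the principal branch")
  }
  out[!is.na(z) & is.infinite(z)] <- Inf
  idx <- which(!is.na(z) & is.finite(z))
  if (!length(idx)) return(out)
  zz <- z[idx]
  w <- numeric(length(zz))
  # initial guesses by regime
  big <- zz > 3
  w[big] <- {
    l <- log(zz[big])
    l - log(l)
  }
  mid <- !big & zz > -0.25
  w[mid] <- {
    x <- zz[mid]
    # series around 0, clipped to avoid a poor start near z = 3
    pmax(pmin(x * (1 - x + 1.5 * x^2), 1.2), -0.25)
  }
  lo <- !big & !mid
  w[lo] <- {
    # near the branch point use the square-root expansion
    p <- sqrt(2 * (exp(1) * zz[lo] + 1))
    -1 + p - p^2 / 3 + 11 * p^3 / 72
  }
  for (iter in 1:100) {
    ew <- exp(w)
    f <- w * ew - zz
    # Halley's iteration
    wp1 <- w + 1
    delta <- f / (ew * wp1 - (w + 2) * f / (2 * wp1))
    w <- w - delta
    if (all(abs(delta) <= 1e-13 * (abs(w) + 1e-13))) break
  }
  out[idx] <- w
  out
}

# log(1 - exp(a)) for a <= 0, computed stably
log1mexp <- function(a) {
  ifelse(a > -log(2), log(-expm1(a)), log1p(-exp(a)))
}

# log(sum(exp(x))) without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# central-difference gradient
num_gradient <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- eps * max(abs(x[i]), 1)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# central-difference Hessian (symmetrised)
num_hessian <- function(f, x, eps = 1e-5) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  h <- eps * pmax(abs(x), 1)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# run expr with a temporary seed when one is supplied, restoring RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
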