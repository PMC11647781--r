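#' Goodness-of-fit statistics for a fitted cdf
#'
#' One-sample Kolmogorov-Smirnov, Cramer-von Mises and Anderson-Darling
#' statistics evaluated against an arbitrary fitted cdf:
#' \deqn{D = \max_i \max\left(\tfrac{i}{n} - F(x_{(i)}),\
#'   F(x_{(i)}) - \tfrac{i-1}{n}\right),}
#' \deqn{W^2 = \frac{1}{12n} + \sum_i \left[F(x_{(i)}) -
#'   \tfrac{2i-1}{2n}\right]^2,}
#' \deqn{A^2 = -n - \frac{1}{n}\sum_i (2i-1)\left[\log F(x_{(i)}) +
#'   \log(1-F(x_{(n+1-i)}))\right].}
#' The KS p-value uses the asymptotic Kolmogorov series at
#' \eqn{\sqrt{n}D} without adjustment for estimated parameters, so it is
#' approximate (and conventionally anti-conservative) when the cdf was
#' fitted to the same data.
#'
#' @param x positive sample (numeric vector or [tlbhe_sample]); sorted
#'   internally.
#' @param cdf_fn vectorised cdf callable on the sample support.
#' @return `ks_statistic`: list with `statistic` and `p.value`;
#'   `cvm_statistic`, `ad_statistic`: the scalar statistic.
#' @examples
#' x <- rtlbhe(100, 1, 1.5, seed = 1)
#' ks_statistic(x, function(q) ptlbhe(q, 1, 1.5))
#' @export
ks_statistic <- function(x, cdf_fn) {
  v <- sort(as.numeric(if (inherits(x, "tlbhe_sample")) x$values else x))
  n <- length(v)
  Fv <- cdf_fn(v)
  i <- seq_len(n)
  D <- max(pmax(i / n - Fv, Fv - (i - 1) / n))
  list(statistic = D, p.value = .kolmogorov_pvalue(sqrt(n) * D))
}

# asymptotic Kolmogorov tail probability Q(t) = 2 sum (-1)^{k-1} e^{-2k^2t^2}
.kolmogorov_pvalue <- function(t) {
  if (t < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' @rdname ks_statistic
#' @export
cvm_statistic <- function(x, cdf_fn) {
  v <- sort(as.numeric(if (inherits(x, "tlbhe_sample")) x$values else x))
  n <- length(v)
  Fv <- cdf_fn(v)
  1 / (12 * n) + sum((Fv - (2 * seq_len(n) - 1) / (2 * n))^2)
}

#' @rdname ks_statistic
#' @export
ad_statistic <- function(x, cdf_fn) {
  v <- sort(as.numeric(if (inherits(x, "tlbhe_sample")) x$values else x))
  n <- length(v)
  Fv <- .clipF(cdf_fn(v))
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(Fv[i]) + log(1 - Fv[n + 1 - i])))
}

#' Information criteria from a minimised negative log-likelihood
#'
#' \eqn{AIC = 2k + 2\,\mathrm{nll}};
#' \eqn{CAIC = AIC + 2k(k+1)/(n-k-1)} (the small-sample AICc
#' correction); \eqn{BIC = k\log n + 2\,\mathrm{nll}};
#' \eqn{HQIC = 2k\log\log n + 2\,\mathrm{nll}}.
#'
#' @param nll minimised negative log-likelihood.
#' @param k number of fitted parameters.
#' @param n sample size (must exceed `k + 1` for CAIC).
#' @return named numeric vector `c(AIC, CAIC, BIC, HQIC)`.
#' @examples
#' information_criteria(23.3765, k = 2, n = 63)
#' @export
information_criteria <- function(nll, k, n) {
  if (k > 0 && n <= k + 1) stop("CAIC requires n > k + 1")
  aic <- 2 * k + 2 * nll
  c(AIC = aic,
    CAIC = aic + if (k > 0) 2 * k * (k + 1) / (n - k - 1) else 0,
    BIC = k * base::log(n) + 2 * nll,
    HQIC = 2 * k * base::log(base::log(n)) + 2 * nll)
}

#' Reference fits with full goodness-of-fit reports
#'
#' Fits one of the candidate lifetime models to a positive sample and
#' assembles a comparison report: estimates, standard errors, minimised
#' negative log-likelihood, the four information criteria and the
#' KS/CvM/AD statistics.
#'
#' Models: `"tlbhe"` (2-parameter, via [tlbhe_fit()]), `"bhe"` (the
#' 1-parameter baseline, 1-D MLE), `"weibull"` with density
#' \eqn{\theta\beta x^{\beta-1} e^{-\theta x^\beta}} (2-D MLE), and
#' `"exp"` whose MLE is the closed form \eqn{\hat\lambda = n/\sum x}.
#'
#' @param x positive sample.
#' @param model one of `"tlbhe"`, `"bhe"`, `"weibull"`, `"exp"`.
#' @return object of class `tlbhe_gof`: list with `model`, `estimate`,
#'   `se`, `nll`, `ic`, `ks`, `ks_pvalue`, `cvm`, `ad`, `n`, `cdf_fn`.
#' @examples
#' x <- rtlbhe(80, 1, 1.5, seed = 5)
#' tlbhe_gof(x, model = "exp")
#' @export
tlbhe_gof <- function(x, model = c("tlbhe", "bhe", "weibull", "exp")) {
  model <- match.arg(model)
  v <- sample_values(x)
  n <- length(v)
  if (model == "tlbhe") {
    fit <- tlbhe_fit(v, method = "ml")
    est <- fit$estimate
    se <- fit$se
    nll <- fit$objective
    cdf_fn <- function(q) ptlbhe(q, est[["rate"]], est[["shape"]])
  } else if (model == "bhe") {
    nllfun <- function(lr) {
      val <- -sum(dbhe(v, exp(lr), log = TRUE))
      if (is.finite(val)) val else .Machine$double.xmax
    }
    opt <- stats::optimize(nllfun, interval = log(1 / mean(v)) + c(-8, 8),
                           tol = 1e-12)
    rate <- exp(opt$minimum)
    nll <- opt$objective
    h <- num_hessian(function(p) -sum(dbhe(v, p, log = TRUE)), rate)
    est <- c(rate = rate)
    se <- c(rate = sqrt(1 / h[1, 1]))
    cdf_fn <- function(q) pbhe(q, rate)
  } else if (model == "weibull") {
    if (stats::sd(v) == 0) stop("degenerate sample: Weibull fit undefined")
    nllfun <- function(par) {
      th <- exp(par[1]); be <- exp(par[2])
      val <- -sum(base::log(th) + base::log(be) + (be - 1) * base::log(v) -
                    th * v^be)
      if (is.finite(val)) val else .Machine$double.xmax
    }
    o <- stats::optim(c(log(1 / mean(v)), 0), nllfun, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    o <- stats::optim(o$par, nllfun, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    th <- exp(o$par[1]); be <- exp(o$par[2])
    nll <- o$value
    H <- num_hessian(function(p)
      -sum(base::log(p[1]) + base::log(p[2]) + (p[2] - 1) * base::log(v) -
             p[1] * v^p[2]), c(th, be))
    V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
    est <- c(theta = th, beta = be)
    se <- stats::setNames(sqrt(pmax(diag(V), 0)), names(est))
    cdf_fn <- function(q) -expm1(-th * pmax(q, 0)^be)
  } else {
    lambda <- n / sum(v)
    est <- c(lambda = lambda)
    se <- c(lambda = lambda / sqrt(n))
    nll <- -sum(stats::dexp(v, lambda, log = TRUE))
    cdf_fn <- function(q) stats::pexp(q, lambda)
  }
  ks <- ks_statistic(v, cdf_fn)
  out <- list(model = model, estimate = est, se = se, nll = nll,
              ic = information_criteria(nll, length(est), n),
              ks = ks$statistic, ks_pvalue = ks$p.value,
              cvm = cvm_statistic(v, cdf_fn), ad = ad_statistic(v, cdf_fn),
              n = n, cdf_fn = cdf_fn)
  class(out) <- "tlbhe_gof"
  out
}

#' @export
print.tlbhe_gof <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): nll = %.4f\n", x$model, x$n, x$nll))
  est <- rbind(estimate = x$estimate, se = x$se)
  print(round(est, 5))
  cat(paste(names(x$ic), round(x$ic, 4), collapse = ", "), "\n")
  cat(sprintf("KS = %.4f (p = %.4f), CvM = %.4f, AD = %.4f\n",
              x$ks, x$ks_pvalue, x$cvm, x$ad))
  invisible(x)
}

#' Model comparison table
#'
#' Fits each requested model and stacks the goodness-of-fit reports
#' into a data frame ordered as requested (one row per model).
#'
#' @param x positive sample.
#' @param models character vector of models to fit (see [tlbhe_gof()]).
#' @return data.frame with columns `model`, `params`, `nll`, `AIC`,
#'   `CAIC`, `BIC`, `HQIC`, `CvM`, `AD`, `KS`, `KS_pvalue`.
#' @examples
#' x <- rtlbhe(60, 1, 1.5, seed = 9)
#' tlbhe_gof_compare(x, models = c("tlbhe", "exp"))
#' @export
tlbhe_gof_compare <- function(x, models = c("tlbhe", "bhe", "weibull",
                                            "exp")) {
  rows <- lapply(models, function(m) {
    g <- tlbhe_gof(x, model = m)
    data.frame(model = m,
               params = paste(sprintf("%s=%.4g", names(g$estimate),
                                      g$estimate), collapse = ", "),
               nll = g$nll, AIC = g$ic[["AIC"]], CAIC = g$ic[["CAIC"]],
               BIC = g$ic[["BIC"]], HQIC = g$ic[["HQIC"]],
               CvM = g$cvm, AD = g$ad, KS = g$ks, KS_pvalue = g$ks_pvalue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
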