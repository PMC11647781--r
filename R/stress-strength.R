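#' Single-component stress-strength reliability
#'
#' \eqn{R = P(W < V)} for independent TL-BHE strength \eqn{V} and stress
#' \eqn{W}, computed as \eqn{\int_0^\infty f_V(x) F_W(x)\,dx} by
#' adaptive quadrature on the exact density and cdf. A common shape
#' parameter is not required.
#'
#' @param strength,stress [tlbhe_params] objects for the strength and
#'   stress distributions.
#' @return probability in \eqn{[0, 1]}.
#' @examples
#' ss_reliability(tlbhe_params(0.5, 1.5), tlbhe_params(2, 1.5))
#' @export
ss_reliability <- function(strength, stress) {
  if (!inherits(strength, "tlbhe_params") || !inherits(stress, "tlbhe_params"))
    stop("'strength' and 'stress' must be tlbhe_params objects")
  g <- function(x) dtlbhe(x, strength) * ptlbhe(x, stress)
  val <- .tlbhe_quad(g, strength, abs_tol = 1e-9)
  min(max(val, 0), 1)
}

#' Multicomponent stress-strength reliability
#'
#' Probability that at least `s` of `k` iid TL-BHE component strengths
#' exceed a common TL-BHE stress:
#' \deqn{Q_{s,k} = \sum_{i=s}^{k} \binom{k}{i} \int_0^\infty
#'   [1-F_{str}(x)]^i\,[F_{str}(x)]^{k-i}\, f_{stress}(x)\,dx.}
#' Nonincreasing in `s` for fixed `k`; `s = k = 1` reduces to
#' [ss_reliability()].
#'
#' @inheritParams ss_reliability
#' @param s minimum number of working components, `1 <= s <= k`.
#' @param k total number of components.
#' @return probability in \eqn{[0, 1]}.
#' @examples
#' ss_reliability_multi(tlbhe_params(0.5, 1.5), tlbhe_params(2, 1.5),
#'                      s = 2, k = 4)
#' @export
ss_reliability_multi <- function(strength, stress, s, k) {
  if (s < 1 || s > k || s != round(s) || k != round(k))
    stop("need integers 1 <= s <= k")
  total <- 0
  for (i in s:k) {
    g <- function(x) {
      lS <- stlbhe(x, strength, log.p = TRUE)
      lF <- ptlbhe(x, strength, log.p = TRUE)
      t1 <- i * lS
      t2 <- (k - i) * lF
      t2[lF == -Inf & k == i] <- 0
      exp(t1 + t2 + dtlbhe(x, stress, log = TRUE))
    }
    total <- total + choose(k, i) * .tlbhe_quad(g, stress, abs_tol = 1e-9)
  }
  min(max(total, 0), 1)
}

#' Series expansion of the single-component reliability (diagnostic)
#'
#' Evaluates a truncated quadruple series for \eqn{P(W < V)} obtained by
#' binomially expanding both Topp-Leone brackets and the two
#' \eqn{(1+\pi x)^{-m}} factors, then integrating term by term:
#' \deqn{R = 2\alpha_1\pi_1 \sum_{i,j,k,l} (-1)^{i+j+k+l}
#'   \binom{\alpha_1-1}{i}\binom{\alpha_2}{j}\binom{2(i+1)+k}{k}
#'   \binom{2j+l-1}{l} \pi_1^k \pi_2^l
#'   \left[\frac{2\,\Gamma(k+l+1)}{\lambda^{k+l+1}} +
#'   \frac{\pi_1\,\Gamma(k+l+2)}{\lambda^{k+l+2}}\right],}
#' with \eqn{\lambda = 2(\pi_1(i+1) + \pi_2 j)}. The inner power-series
#' expansions are valid only for \eqn{\pi x < 1}, so the term-by-term
#' integral can diverge; partial sums are monitored and quadrature is
#' always returned as the authoritative value alongside the series and
#' their discrepancy.
#'
#' @inheritParams ss_reliability
#' @param truncation length-4 integer vector of truncation orders for
#'   the indices \eqn{(i, j, k, l)}.
#' @return list with `series`, `quadrature`, `discrepancy` and the
#'   divergence flag `diverged`.
#' @examples
#' ss_reliability_series(tlbhe_params(1, 1), tlbhe_params(1, 1),
#'                       truncation = c(5, 5, 5, 5))
#' @export
ss_reliability_series <- function(strength, stress,
                                  truncation = c(10, 10, 10, 10)) {
  if (length(truncation) != 4 || any(truncation < 0))
    stop("'truncation' must be four non-negative integers")
  if (!isTRUE(all.equal(strength$shape, stress$shape)))
    warning("series expansion assumes a common shape parameter; ",
            "strength and stress shapes differ")
  p1 <- strength$rate; a1 <- strength$shape
  p2 <- stress$rate; a2 <- stress$shape
  total <- 0
  running <- numeric(0)
  for (i in 0:truncation[1]) for (j in 0:truncation[2]) {
    lam <- 2 * (p1 * (i + 1) + p2 * j)
    k <- 0:truncation[3]
    for (l in 0:truncation[4]) {
      term <- (-1)^(i + j + k + l) * choose(a1 - 1, i) * choose(a2, j) *
        choose(2 * (i + 1) + k, k) * choose(2 * j + l - 1, l) *
        p1^k * p2^l *
        (2 * gamma(k + l + 1) / lam^(k + l + 1) +
           p1 * gamma(k + l + 2) / lam^(k + l + 2))
      total <- total + sum(term)
    }
    running <- c(running, total)
  }
  series <- 2 * a1 * p1 * total
  quad <- ss_reliability(strength, stress)
  tail_sums <- 2 * a1 * p1 * utils::tail(running, 5)
  diverged <- !is.finite(series) || series < -0.05 || series > 1.05 ||
    (length(tail_sums) >= 3 &&
       stats::sd(tail_sums) > 0.1 * max(abs(quad), 1e-12))
  list(series = series, quadrature = quad,
       discrepancy = abs(series - quad), diverged = diverged)
}
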