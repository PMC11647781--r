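#' Monte-Carlo bias/MSE study of the classical estimators
#'
#' Replicates the standard estimator-comparison design: for each sample
#' size in `n_grid`, `n_reps` samples are drawn from
#' TL-BHE(`rate`, `shape`), each requested estimator is applied, and
#' bias, MSE, RMSE and the Monte-Carlo standard error of the bias are
#' accumulated per parameter. Replicates are seeded individually
#' (`seed` plus a deterministic offset per cell and replicate) so any
#' cell can be reproduced in isolation. Non-convergent fits are counted
#' and excluded; a cell with more than 5\% failures is flagged in the
#' `warnings` attribute.
#'
#' @param rate,shape true parameter values.
#' @param n_grid sample sizes (default `c(50, 100, 150, 200)`).
#' @param n_reps replications per cell (default 1000).
#' @param methods subset of the seven classical estimators.
#' @param seed integer base seed.
#' @return data.frame of class `tlbhe_simreport` with one row per
#'   (method, parameter, n): columns `method`, `parameter`, `n`,
#'   `bias`, `mse`, `rmse`, `mc_se`, `n_fail`.
#' @examples
#' run_bias_mse_study(0.7, 1.5, n_grid = 50, n_reps = 20,
#'                    methods = "ml", seed = 1)
#' @export
run_bias_mse_study <- function(rate, shape, n_grid = c(50, 100, 150, 200),
                               n_reps = 1000,
                               methods = c("ml", "mps", "ls", "wls", "cvm",
                                           "ad", "rtad"),
                               seed = 1) {
  if (n_reps < 2) stop("'n_reps' must be at least 2")
  methods <- match.arg(methods, several.ok = TRUE)
  truth <- c(rate = rate, shape = shape)
  rows <- list()
  warns <- character(0)
  for (ni in seq_along(n_grid)) {
    n <- n_grid[ni]
    est <- array(NA_real_, dim = c(n_reps, 2, length(methods)),
                 dimnames = list(NULL, names(truth), methods))
    for (r in seq_len(n_reps)) {
      x <- rtlbhe(n, rate, shape, seed = seed + ni * 100000L + r)
      for (m in methods) {
        fit <- tryCatch(tlbhe_fit(x, method = m), error = function(e) NULL)
        if (!is.null(fit) && fit$converged) est[r, , m] <- fit$estimate
      }
    }
    for (m in methods) {
      n_fail <- sum(is.na(est[, 1, m]))
      if (n_fail > 0.05 * n_reps)
        warns <- c(warns, sprintf("%s at n=%d: %d/%d failures",
                                  m, n, n_fail, n_reps))
      for (par in names(truth)) {
        e <- est[, par, m]
        e <- e[!is.na(e)]
        err <- e - truth[[par]]
        rows[[length(rows) + 1]] <- data.frame(
          method = m, parameter = par, n = n,
          bias = mean(err), mse = mean(err^2),
          rmse = sqrt(mean(err^2)),
          mc_se = stats::sd(err) / sqrt(length(err)),
          n_fail = n_fail, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  attr(out, "warnings") <- warns
  class(out) <- c("tlbhe_simreport", class(out))
  out
}

#' Monte-Carlo study of the Bayes point estimators
#'
#' As [run_bias_mse_study()] but each replicate runs the
#' Metropolis-Hastings sampler and records the SEL, LINEX
#' (\eqn{\nu \in} `nu`) and GEL (\eqn{\tau \in} `tau`) point estimates.
#' The per-replicate chain length defaults to the study convention
#' (10000 draws, 2000 burn-in) but can be reduced for speed; the report
#' records the configuration used.
#'
#' @inheritParams run_bias_mse_study
#' @param prior a [tlbhe_prior].
#' @param n_draws,burn_in per-replicate chain configuration.
#' @param nu LINEX parameters (default `c(-1.5, 1.5)`).
#' @param tau GEL parameters (default `c(-0.5, 0.5)`).
#' @return data.frame as in [run_bias_mse_study()], with `method` one of
#'   `"sel"`, `"linex(nu)"`, `"gel(tau)"`.
#' @examples
#' run_bayes_study(0.7, 1.5, n_grid = 50, n_reps = 3,
#'                 n_draws = 600, burn_in = 100, seed = 1)
#' @export
run_bayes_study <- function(rate, shape, n_grid = c(50, 100, 150, 200),
                            n_reps = 1000, prior = tlbhe_prior(),
                            n_draws = 10000, burn_in = 2000,
                            nu = c(-1.5, 1.5), tau = c(-0.5, 0.5),
                            seed = 1) {
  truth <- c(rate = rate, shape = shape)
  labels <- c("sel",
              sprintf("linex(%g)", nu),
              sprintf("gel(%g)", tau))
  rows <- list()
  for (ni in seq_along(n_grid)) {
    n <- n_grid[ni]
    est <- array(NA_real_, dim = c(n_reps, 2, length(labels)),
                 dimnames = list(NULL, names(truth), labels))
    for (r in seq_len(n_reps)) {
      s <- seed + ni * 100000L + r
      x <- rtlbhe(n, rate, shape, seed = s)
      d <- tryCatch(
        tlbhe_mh(x, prior = prior, n_draws = n_draws, burn_in = burn_in,
                 seed = s + 50000L),
        error = function(e) NULL)
      if (is.null(d)) next
      est[r, , "sel"] <- tlbhe_point_estimates(d, "sel")
      for (v in nu)
        est[r, , sprintf("linex(%g)", v)] <-
          tlbhe_point_estimates(d, "linex", nu = v)
      for (tt in tau)
        est[r, , sprintf("gel(%g)", tt)] <-
          tlbhe_point_estimates(d, "gel", tau = tt)
    }
    for (m in labels) for (par in names(truth)) {
      e <- est[, par, m]
      n_fail <- sum(is.na(e))
      e <- e[!is.na(e)]
      err <- e - truth[[par]]
      rows[[length(rows) + 1]] <- data.frame(
        method = m, parameter = par, n = n,
        bias = mean(err), mse = mean(err^2), rmse = sqrt(mean(err^2)),
        mc_se = stats::sd(err) / sqrt(length(err)),
        n_fail = n_fail, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  attr(out, "config") <- list(n_draws = n_draws, burn_in = burn_in,
                              nu = nu, tau = tau)
  class(out) <- c("tlbhe_simreport", class(out))
  out
}

#' Interval coverage study
#'
#' Empirical coverage and mean width of ML Wald intervals and/or
#' equal-tail Bayes credible intervals at a nominal level, over seeded
#' replicates from the true distribution.
#'
#' @inheritParams run_bayes_study
#' @param level nominal coverage level.
#' @param methods subset of `c("ml", "bayes")`.
#' @return data.frame with one row per (method, parameter, n):
#'   `coverage`, `mean_width`, `n_used`.
#' @examples
#' run_coverage_study(0.7, 1.5, n_grid = 50, n_reps = 10,
#'                    methods = "ml", seed = 1)
#' @export
run_coverage_study <- function(rate, shape, n_grid = c(50, 100, 150, 200),
                               n_reps = 1000, level = 0.95,
                               methods = c("ml", "bayes"),
                               prior = tlbhe_prior(),
                               n_draws = 3000, burn_in = 1000, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  truth <- c(rate = rate, shape = shape)
  rows <- list()
  for (ni in seq_along(n_grid)) {
    n <- n_grid[ni]
    hits <- widths <- array(NA_real_, dim = c(n_reps, 2, length(methods)),
                            dimnames = list(NULL, names(truth), methods))
    for (r in seq_len(n_reps)) {
      s <- seed + ni * 100000L + r
      x <- rtlbhe(n, rate, shape, seed = s)
      if ("ml" %in% methods) {
        fit <- tryCatch(tlbhe_fit(x, method = "ml", level = level),
                        error = function(e) NULL)
        if (!is.null(fit) && all(is.finite(fit$ci))) {
          hits[r, , "ml"] <- truth >= fit$ci[, "lower"] &
            truth <= fit$ci[, "upper"]
          widths[r, , "ml"] <- fit$ci[, "upper"] - fit$ci[, "lower"]
        }
      }
      if ("bayes" %in% methods) {
        d <- tryCatch(
          tlbhe_mh(x, prior = prior, n_draws = n_draws, burn_in = burn_in,
                   seed = s + 50000L),
          error = function(e) NULL)
        if (!is.null(d)) {
          ci <- tlbhe_credible_interval(d, level = level)
          hits[r, , "bayes"] <- truth >= ci[, "lower"] & truth <= ci[, "upper"]
          widths[r, , "bayes"] <- ci[, "upper"] - ci[, "lower"]
        }
      }
    }
    for (m in methods) for (par in names(truth)) {
      h <- hits[, par, m]
      rows[[length(rows) + 1]] <- data.frame(
        method = m, parameter = par, n = n, level = level,
        coverage = mean(h, na.rm = TRUE),
        mean_width = mean(widths[, par, m], na.rm = TRUE),
        n_used = sum(!is.na(h)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
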