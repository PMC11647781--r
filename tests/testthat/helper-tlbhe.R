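# shared fixtures: the parameter grid used by the property tests and a
# couple of small deterministic samples
param_grid <- expand.grid(rate = c(0.1, 0.5, 1, 5),
                          shape = c(0.3, 1, 2, 10))

toy_sample <- function(n = 40, rate = 1, shape = 1.5, seed = 123) {
  rtlbhe(n, rate, shape, seed = seed)
}

# effective sample size from the lag-k autocorrelations (initial positive
# sequence), for Monte-Carlo standard errors of chain means
ess <- function(x) {
  n <- length(x)
  rho <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  k <- if (length(pos)) pos[1] - 1 else length(rho)
  max(n / (1 + 2 * sum(rho[seq_len(k)])), 10)
}
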