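test_that("negative log-likelihood matches the density and Eq-style sum", {
  # single observation at x = 1: -log(0.75 * exp(-2)) = 2 - log(0.75)
  expect_equal(tlbhe_negloglik(list(rate = 1, shape = 1), 1),
               2 - log(0.75), tolerance = 1e-10)
  x <- toy_sample(60)
  p <- list(rate = 0.8, shape = 1.7)
  expect_equal(tlbhe_negloglik(p, x),
               -sum(dtlbhe(sort(x), p$rate, p$shape, log = TRUE)),
               tolerance = 1e-8)
  # non-finite log-density (shape < 1 would be fine, but an inadmissible
  # point must return +Inf, not NaN)
  expect_identical(tlbhe_negloglik(list(rate = 1, shape = 2), c(0.5, 0.5)),
                   -sum(dtlbhe(c(0.5, 0.5), 1, 2, log = TRUE)))
})

test_that("MPS spacings telescope and tied samples are handled", {
  x <- toy_sample(30)
  p <- list(rate = 0.5, shape = 2)
  Fv <- ptlbhe(sort(x), p$rate, p$shape)
  expect_equal(sum(diff(c(0, Fv, 1))), 1, tolerance = 1e-12)
  # ties do not produce -Inf/Inf objectives
  xt <- c(1, 1, 1, 2, 3)
  expect_true(is.finite(tlbhe_mps_objective(p, xt)))
})

test_that("objective formulas match direct plug-in computations", {
  x <- sort(toy_sample(20))
  n <- length(x)
  p <- list(rate = 1.2, shape = 0.9)
  Fv <- ptlbhe(x, p$rate, p$shape)
  i <- seq_len(n)
  expect_equal(tlbhe_ls_objective(p, x), sum((Fv - i / (n + 1))^2))
  # WLS weights for n = 3 from the formula (n+1)^2 (n+2) / (i(n-i+1)):
  # {80/3, 20, 80/3}
  w3 <- (3 + 1)^2 * (3 + 2) / (1:3 * (3 - 1:3 + 1))
  expect_equal(w3, c(80 / 3, 20, 80 / 3))
  expect_equal(tlbhe_cvm_objective(p, x),
               1 / (12 * n) + sum((Fv - (2 * i - 1) / (2 * n))^2))
  expect_gte(tlbhe_cvm_objective(p, x), 1 / (12 * n))
  # AD depends only on the sorted values
  xp <- sample(x)
  expect_equal(tlbhe_ad_objective(p, xp), tlbhe_ad_objective(p, x))
  expect_equal(tlbhe_rtad_objective(p, xp), tlbhe_rtad_objective(p, x))
})

test_that("perfect plug-in samples are recovered exactly", {
  p <- tlbhe_params(1.3, 2.2)
  n <- 60
  # LS: sample at the i/(n+1) quantiles -> objective 0 at truth
  xl <- qtlbhe(seq_len(n) / (n + 1), p)
  expect_lt(tlbhe_ls_objective(p, xl), 1e-18)
  fit <- tlbhe_fit(xl, method = "ls")
  expect_equal(unname(fit$estimate), c(p$rate, p$shape), tolerance = 1e-3)
  # CvM: sample at the (2i-1)/(2n) quantiles attains the floor 1/(12n)
  xc <- qtlbhe((2 * seq_len(n) - 1) / (2 * n), p)
  expect_equal(tlbhe_cvm_objective(p, xc), 1 / (12 * n), tolerance = 1e-15)
  # AD at truth on the plug-in sample sits near its small-sample floor
  x50 <- qtlbhe((2 * 1:50 - 1) / 100, p)
  expect_lt(tlbhe_ad_objective(p, x50), 0.3)
})

test_that("all seven estimators recover the truth on large samples", {
  x <- rtlbhe(5000, 0.5, 2, seed = 11)
  for (m in c("ml", "mps", "ls", "wls", "cvm", "ad", "rtad")) {
    fit <- tlbhe_fit(x, method = m)
    expect_true(fit$converged, label = paste(m, "converged"))
    expect_lt(abs(fit$estimate[["rate"]] - 0.5), 0.05)
    expect_lt(abs(fit$estimate[["shape"]] - 2), 0.15)
    # stored objective equals re-evaluation at the stored params
    objfn <- switch(m, ml = tlbhe_negloglik, mps = tlbhe_mps_objective,
                    ls = tlbhe_ls_objective, wls = tlbhe_wls_objective,
                    cvm = tlbhe_cvm_objective, ad = tlbhe_ad_objective,
                    rtad = tlbhe_rtad_objective)
    expect_equal(fit$objective, objfn(fit$params, x), tolerance = 1e-8)
  }
  # ML within 5% of truth at n = 5000
  fml <- tlbhe_fit(x, "ml")
  expect_lt(abs(fml$estimate[["rate"]] / 0.5 - 1), 0.05)
  expect_lt(abs(fml$estimate[["shape"]] / 2 - 1), 0.05)
})

test_that("MPS and ML agree asymptotically", {
  x <- rtlbhe(2000, 0.7, 1.5, seed = 21)
  fml <- tlbhe_fit(x, "ml")
  fmps <- tlbhe_fit(x, "mps")
  d <- abs(fml$estimate - fmps$estimate)
  expect_true(all(d < 2 * fml$se))
})

test_that("ML standard errors: Wald intervals and bootstrap agreement", {
  x <- rtlbhe(200, 0.7, 1.5, seed = 31)
  fit <- tlbhe_fit(x, "ml", level = 0.95)
  expect_true(all(fit$ci[, "lower"] < fit$ci[, "upper"]))
  expect_equal(unname(fit$ci[, "upper"] - fit$estimate),
               unname(qnorm(0.975) * fit$se), tolerance = 1e-10)
  bse <- tlbhe_boot_se(x, "ml", B = 500, seed = 5)
  expect_lt(abs(bse[["rate"]] / fit$se[["rate"]] - 1), 0.10)
  expect_lt(abs(bse[["shape"]] / fit$se[["shape"]] - 1), 0.10)
})

test_that("fit input validation", {
  expect_error(tlbhe_fit(c(1, 2), "ml"), "at least 3")
  expect_error(tlbhe_fit(c(1, -2, 3), "ml"), "positive")
  expect_error(tlbhe_fit(toy_sample(10), "unknown"))
})
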