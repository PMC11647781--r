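test_that("density matches hand-derived values and handles the origin", {
  # 0.75 * exp(-2), verified against a 50-digit substitution oracle
  expect_equal(dtlbhe(1, rate = 1, shape = 1), 0.1015014624274595,
               tolerance = 1e-12)
  # at x = 0 the bracket term has exponent 0 for shape 1: f(0) = 4*rate
  expect_equal(dtlbhe(0, rate = 2, shape = 1), 8)
  expect_equal(dtlbhe(0, rate = 3, shape = 2), 0)
  expect_error(dtlbhe(-1, rate = 1, shape = 1), "non-negative")
  expect_error(tlbhe_params(-1, 1), "positive")
  expect_error(tlbhe_params(1, 0), "positive")
})

test_that("pdf integrates to 1 over the parameter grid", {
  for (i in seq_len(nrow(param_grid))) {
    p <- tlbhe_params(param_grid$rate[i], param_grid$shape[i])
    val <- integrate(dtlbhe, 0, Inf, rate = p, abs.tol = 1e-10,
                     rel.tol = 1e-10)$value
    expect_equal(val, 1, tolerance = 1e-8,
                 label = sprintf("normalization at rate=%g shape=%g",
                                 p$rate, p$shape))
  }
})

test_that("cdf, survival and hazard are mutually consistent", {
  expect_equal(ptlbhe(1, 1, 1), 1 - exp(-2) / 4, tolerance = 1e-12)
  expect_equal(ptlbhe(0, 2, 5), 0)
  xs <- c(0.01, 0.1, 0.5, 1, 3, 10, 50)
  for (i in seq_len(nrow(param_grid))) {
    p <- tlbhe_params(param_grid$rate[i], param_grid$shape[i])
    Fv <- ptlbhe(xs, p)
    expect_true(all(diff(Fv) >= 0))
    expect_true(all(Fv >= 0 & Fv <= 1))
    expect_equal(Fv + stlbhe(xs, p), rep(1, length(xs)), tolerance = 1e-12)
    sf <- stlbhe(xs, p)
    ok <- sf > 1e-300
    expect_equal(htlbhe(xs, p)[ok], (dtlbhe(xs, p) / sf)[ok],
                 tolerance = 1e-10)
  }
  # deep tail: survival must keep relative accuracy where cdf ~ 1
  s <- stlbhe(60, 1, 1)
  expect_gt(s, 0)
  expect_lt(s, 1e-40)
  # hazard of shape = 1 decreases on (0, 3), consistent with the
  # decreasing / reversed-bathtub shapes of the family
  h <- htlbhe(seq(0.01, 3, length.out = 60), 1, 1)
  expect_true(all(diff(h) < 0))
  # hazard at 0 for shape 1 equals the density there
  expect_equal(htlbhe(0, 2, 1), 8)
})

test_that("quantile function inverts the cdf via Lambert W", {
  expect_equal(qtlbhe(0, 1, 1), 0)
  # median frozen from a bisection oracle on cdf(x) = 0.5
  expect_equal(qtlbhe(0.5, 1, 1), 0.1805734, tolerance = 1e-6)
  u <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  for (i in seq_len(nrow(param_grid))) {
    p <- tlbhe_params(param_grid$rate[i], param_grid$shape[i])
    x <- qtlbhe(u, p)
    expect_equal(ptlbhe(x, p), u, tolerance = 1e-10)
    xs <- qtlbhe(c(0.1, 0.4, 0.9), p)
    expect_equal(qtlbhe(ptlbhe(xs, p), p), xs, tolerance = 1e-8)
  }
  # extreme upper tail stays finite and monotone
  qq <- qtlbhe(c(0.999, 0.999999, 1 - 1e-12), 1, 1)
  expect_true(all(is.finite(qq)) && all(diff(qq) > 0))
  expect_error(qtlbhe(1, 1, 1), "probabilities")
  expect_error(qtlbhe(-0.1, 1, 1), "probabilities")
})

test_that("lambert_w0 solves w exp(w) = z on the principal branch", {
  z <- c(0, 0.5, 1, exp(1), 10, 1e4, 1e100, -0.3, -exp(-1) + 1e-9)
  w <- lambert_w0(z)
  expect_equal(w * exp(w), z, tolerance = 1e-10)
  expect_equal(lambert_w0(exp(1)), 1, tolerance = 1e-12)
  expect_error(lambert_w0(-1), "principal")
})

test_that("sampler is reproducible and matches the target law", {
  p <- tlbhe_params(1, 1)
  x1 <- rtlbhe(500, p, seed = 7)
  x2 <- rtlbhe(500, p, seed = 7)
  expect_identical(x1, x2)
  expect_true(all(x1 > 0))
  x <- rtlbhe(1e4, p, seed = 42)
  ks <- suppressWarnings(stats::ks.test(x, function(q) ptlbhe(q, p)))
  expect_gt(ks$p.value, 0.01)
  # shape = 1 is the min of two independent baseline draws
  set.seed(99)
  u1 <- matrix(runif(2e4), ncol = 2)
  # baseline draws via the identity F_{TL,shape=1} = 1-(1-G)^2, so
  # G^{-1}(v) = Q_{TLBHE(1,1)}(1-(1-v)^2)
  xb <- pmin(qtlbhe(1 - (1 - u1[, 1])^2, 1, 1),
             qtlbhe(1 - (1 - u1[, 2])^2, 1, 1))
  ks2 <- suppressWarnings(stats::ks.test(x, xb))
  expect_gt(ks2$p.value, 0.01)
})

test_that("acceptance-rejection sampler agrees with inverse transform", {
  x1 <- rtlbhe_ar(4000, 1, 1, seed = 6)
  x2 <- rtlbhe_ar(4000, 1, 1, seed = 6)
  expect_identical(as.numeric(x1), as.numeric(x2))
  # overall acceptance probability is 1/N for any valid envelope
  expect_equal(attr(x1, "acceptance_rate"), 1 / attr(x1, "N"),
               tolerance = 0.1)
  xr <- rtlbhe(4000, 1, 1, seed = 61)
  expect_gt(suppressWarnings(stats::ks.test(x1, xr))$p.value, 0.01)
  # a heavier-tailed Weibull envelope also works
  x3 <- rtlbhe_ar(2000, 0.7, 1.5, envelope_shape = 0.8,
                  envelope_rate = 0.9, seed = 3)
  expect_gt(suppressWarnings(
    stats::ks.test(x3, function(q) ptlbhe(q, 0.7, 1.5)))$p.value, 0.01)
  # an envelope with a lighter tail is rejected with advice
  expect_error(rtlbhe_ar(10, 1, 1, envelope_shape = 2, envelope_rate = 1),
               "envelope")
})

test_that("moments: quadrature agrees with Monte Carlo and the series
           route reports its truncation health", {
  expect_equal(tlbhe_moment(0, 1, 7), 1)
  m1 <- tlbhe_moment(1, 1, 1)
  x <- rtlbhe(1e5, 1, 1, seed = 8)
  expect_lt(abs(m1 - mean(x)), 3 * sd(x) / sqrt(length(x)))
  # variance non-negative across the grid
  for (i in seq_len(nrow(param_grid))) {
    p <- tlbhe_params(param_grid$rate[i], param_grid$shape[i])
    expect_gte(tlbhe_moment(2, p) - tlbhe_moment(1, p)^2, 0)
  }
  # the series expansion is term-by-term divergent over (0, Inf); it
  # must say so rather than silently return garbage
  sm <- suppressWarnings(tlbhe_moment(1, 1, 1, method = "series",
                                      max_i = 10, max_j = 20))
  expect_false(attr(sm, "converged"))
  expect_warning(tlbhe_moment(1, 1, 1, method = "series", max_j = 20),
                 "not converged")
})

test_that("mgf and characteristic function behave", {
  expect_equal(tlbhe_mgf(0, 2, 3), 1)
  h <- 1e-4
  d <- (tlbhe_mgf(h, 1, 1) - tlbhe_mgf(-h, 1, 1)) / (2 * h)
  expect_equal(d, tlbhe_moment(1, 1, 1), tolerance = 1e-6)
  expect_error(tlbhe_mgf(2, 1, 1), "diverges")
  expect_true(all(Mod(tlbhe_cf(c(0.5, 2, 10), 1, 2)) <= 1 + 1e-9))
})

test_that("entropies: Shannon limit and monotonicity in order", {
  p <- tlbhe_params(1, 1.5)
  expect_equal(tlbhe_renyi_entropy(1 + 1e-4, p), tlbhe_shannon_entropy(p),
               tolerance = 1e-3)
  # order 2 equals -log integral of f^2 by definition
  i2 <- integrate(function(x) dtlbhe(x, p)^2, 0, Inf)$value
  expect_equal(tlbhe_renyi_entropy(2, p), -log(i2), tolerance = 1e-8)
  h <- vapply(c(0.5, 2, 5), tlbhe_renyi_entropy, numeric(1), rate = p)
  expect_true(all(diff(h) <= 0))
  expect_error(tlbhe_renyi_entropy(1, p), "shannon",
               ignore.case = TRUE)
})

test_that("order statistics: reduction, normalization, max identity", {
  p <- tlbhe_params(1, 2)
  x <- c(0.2, 0.7, 1.9)
  expect_equal(dtlbhe_order(x, 1, 1, p), dtlbhe(x, p))
  for (s in c(1, 3, 5)) {
    v <- integrate(dtlbhe_order, 0, Inf, s = s, n = 5, rate = p,
                   rel.tol = 1e-10)$value
    expect_equal(v, 1, tolerance = 1e-7)
  }
  # cdf of the maximum is F^n: integrate the s = n density up to x
  for (xx in c(0.3, 1)) {
    lhs <- integrate(dtlbhe_order, 0, xx, s = 5, n = 5, rate = p)$value
    expect_equal(lhs, ptlbhe(xx, p)^5, tolerance = 1e-7)
  }
  expect_error(dtlbhe_order(1, 0, 5, p), "1:n")
  expect_error(dtlbhe_order(1, 6, 5, p), "1:n")
})

test_that("baseline BHE functions are a proper distribution", {
  expect_equal(integrate(dbhe, 0, Inf, rate = 2)$value, 1, tolerance = 1e-8)
  xs <- c(0.1, 1, 4)
  d <- vapply(xs, function(x)
    (pbhe(x + 1e-6, 2) - pbhe(x - 1e-6, 2)) / 2e-6, numeric(1))
  expect_equal(d, dbhe(xs, 2), tolerance = 1e-5)
})
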