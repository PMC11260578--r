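test_that("dispersion MLE matches a dense grid-search oracle and honours bounds", {
  set.seed(41)
  grid <- exp(seq(log(0.01), log(1000), length.out = 1000))
  for (rep in 1:25) {
    n <- 60
    mu <- runif(1, 20, 300)
    r_true <- exp(runif(1, log(0.05), log(500)))
    k <- matrix(rnbinom(n, mu = mu, size = r_true), ncol = 1)
    ex <- matrix(mu, n, 1)
    fit <- fit_dispersion(k, ex)
    expect_gte(fit, 0.01); expect_lte(fit, 1000)
    ll_fit <- sum(dnbinom(k, size = fit, mu = mu, log = TRUE))
    ll_grid <- max(vapply(grid, function(r)
      sum(dnbinom(k, size = r, mu = mu, log = TRUE)), numeric(1)))
    expect_gte(ll_fit, ll_grid - 1e-6)
  }
})

test_that("dispersion clamps to the bounds on degenerate inputs", {
  set.seed(42)
  # Poisson data (variance = mean) -> upper bound
  k <- matrix(rpois(500, 100), ncol = 1)
  expect_equal(fit_dispersion(k, matrix(100, 500, 1)), 1000)
  # wildly overdispersed -> lower bound
  k2 <- matrix(c(rep(0L, 250), rep(5000L, 250)), ncol = 1)
  expect_equal(fit_dispersion(k2, matrix(50, 500, 1)), 0.01)
})

test_that("dispersion recovery from simulated NB data is within 20%", {
  set.seed(43)
  k <- matrix(rnbinom(500, mu = 50, size = 5), ncol = 1)
  fit <- fit_dispersion(k, matrix(50, 500, 1))
  expect_gt(fit, 4); expect_lt(fit, 6)
})

test_that("the exclusion mask removes flagged entries from the likelihood", {
  set.seed(44)
  k <- matrix(rnbinom(200, mu = 50, size = 20), ncol = 1)
  poisoned <- k; poisoned[1, 1] <- 1e7
  ex <- matrix(50, 200, 1)
  r_poisoned <- fit_dispersion(poisoned, ex)
  excl <- matrix(FALSE, 200, 1); excl[1, 1] <- TRUE
  r_robust <- fit_dispersion(poisoned, ex, exclude = excl)
  expect_lt(r_poisoned, 1)          # single huge count crushes the MLE
  expect_gt(r_robust, 10)           # exclusion restores the bulk estimate
  expect_equal(r_robust, fit_dispersion(k[-1, , drop = FALSE],
                                        ex[-1, , drop = FALSE]))
})

test_that("nb_pvalues implements the doubled two-sided test", {
  # closed form at k = 0: F(0) = (r/(r+mu))^r = (1/101)^1
  p <- nb_pvalues(matrix(0L), matrix(100), dispersions = 1)
  expect_equal(p[1, 1], 2 * (1 / 101), tolerance = 1e-12)

  # observation at the distribution median -> capped at 1
  med <- qnbinom(0.5, size = 5, mu = 100)
  p_med <- nb_pvalues(matrix(med), matrix(100), 5)
  expect_equal(p_med[1, 1], 1)

  # undoubled variant never exceeds 1/2
  p_lit <- nb_pvalues(matrix(med), matrix(100), 5, double = FALSE)
  expect_lte(p_lit[1, 1], 0.5)

  # matches textbook formula on a random grid
  set.seed(45)
  k <- matrix(rnbinom(200, mu = 60, size = 3), 10)
  mu <- matrix(runif(200, 30, 90), 10)
  r <- runif(20, 0.5, 50)
  p2 <- nb_pvalues(k, mu, r)
  rr <- matrix(r, 10, 20, byrow = TRUE)
  ref <- pmin(1, 2 * pmin(0.5, pnbinom(k, size = rr, mu = mu),
                          1 - pnbinom(k - 1, size = rr, mu = mu)))
  expect_equal(p2, ref, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(p2 > 0 & p2 <= 1))
})

test_that("nb test p-values are calibrated under the null", {
  set.seed(46)
  n <- 2e4
  mu <- runif(n, 50, 500)
  r <- exp(runif(n, log(2), log(100)))
  k <- rnbinom(n, mu = mu, size = r)
  p <- nb_pvalues(matrix(k, 1), matrix(mu, 1), dispersions = r)
  # p-values live per region here; pool them (1 sample x n regions)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("adjust_pvalues applies BY per sample and dominates raw p", {
  p1 <- matrix(0.037)
  expect_equal(adjust_pvalues(p1, method = "BH")[1, 1], 0.037)

  set.seed(47)
  p <- matrix(runif(50), 5, 10)
  padj <- adjust_pvalues(p)
  expect_true(all(padj >= p))
  for (i in 1:5)
    expect_equal(unname(padj[i, ]), by_stepup(p[i, ]))
  expect_equal(adjust_pvalues(matrix(1, 3, 4)),
               matrix(1, 3, 4), ignore_attr = TRUE)
  # global scope pools the whole matrix
  pg <- adjust_pvalues(p, scope = "global")
  expect_equal(as.numeric(pg), by_stepup(as.numeric(p)))
})

test_that("effect sizes standardize fold changes per region", {
  k <- matrix(c(3L, 1L, 0L, 8L), 2)
  ex <- matrix(c(1, 1, 2, 2), 2)
  eff <- effect_sizes(k, ex)
  expect_equal(eff$l2fc[1, 1], 1)          # log2(4/2)
  expect_equal(eff$l2fc[k == ex], rep(0, sum(k == ex)))
  set.seed(48)
  k2 <- matrix(rnbinom(300, mu = 50, size = 5), 15)
  eff2 <- effect_sizes(k2, matrix(50, 15, 20))
  expect_equal(unname(colMeans(eff2$zscore)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(eff2$zscore, 2, sd)), rep(1, 20), tolerance = 1e-12)
  # degenerate region -> Z = 0 with warning
  expect_warning(effd <- effect_sizes(matrix(5L, 4), matrix(5, 4)), "zero")
  expect_equal(unname(effd$zscore), matrix(0, 4))
})

test_that("call_outliers applies the three rules with documented boundaries", {
  call1 <- call_outliers(padj = matrix(0.04), l2fc = matrix(0.6),
                         counts = matrix(60L), expected = matrix(10))
  expect_true(call1$is_outlier[1, 1])
  expect_equal(call1$direction[1, 1], 1)

  # count rule fails on both observed and expected
  expect_false(call_outliers(matrix(0.04), matrix(0.6), matrix(10L),
                             matrix(10))$is_outlier[1, 1])
  # boundary: padj exactly alpha, |l2fc| exactly min_l2fc -> no call
  expect_false(call_outliers(matrix(0.05), matrix(0.6), matrix(60L),
                             matrix(60))$is_outlier[1, 1])
  expect_false(call_outliers(matrix(0.04), matrix(0.5), matrix(60L),
                             matrix(60))$is_outlier[1, 1])
  # expected >= 50 suffices even when observed is low (under-outlier)
  expect_true(call_outliers(matrix(0.01), matrix(-3), matrix(0L),
                            matrix(80))$is_outlier[1, 1])
  # lowering alpha never adds calls
  set.seed(49)
  padj <- matrix(runif(100), 10); l2fc <- matrix(rnorm(100), 10)
  k <- matrix(rpois(100, 100), 10)
  c1 <- call_outliers(padj, l2fc, k, k, alpha = 0.05)$is_outlier
  c2 <- call_outliers(padj, l2fc, k, k, alpha = 0.01)$is_outlier
  expect_true(all(c1 | !c2))
})
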