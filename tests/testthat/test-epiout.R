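test_that("fit_encoder returns orthonormal principal axes", {
  set.seed(51)
  x <- matrix(rnorm(40 * 100), 40, 100)
  We <- fit_encoder(x, 5)
  expect_equal(crossprod(We), diag(5), tolerance = 1e-10, ignore_attr = TRUE)

  # rank-1 data: one component explains everything
  x1 <- outer(rnorm(30), rnorm(60))
  W1 <- fit_encoder(x1, 1)
  expect_equal(sum((x1 %*% W1 %*% t(W1) - x1)^2), 0, tolerance = 1e-16)

  # reconstruction error of the q-dim projection = discarded eigenvalues
  q <- 4
  Wq <- fit_encoder(x, q)
  resid <- sum((x - x %*% Wq %*% t(Wq))^2)
  ev <- svd(x)$d^2
  expect_equal(resid, sum(ev[-(1:q)]), tolerance = 1e-6)

  expect_error(fit_encoder(x, 40), "bottleneck")
})

test_that("build_latent concatenates projections and confounders", {
  set.seed(52)
  x <- matrix(rnorm(20 * 50), 20, 50)
  We <- fit_encoder(x, 3)
  H0 <- build_latent(x, We)                       # intercept-only default
  expect_equal(dim(H0), c(20L, 4L))
  expect_equal(unname(H0[, 4]), rep(1, 20))
  expect_equal(H0[, 1:3], x %*% We, ignore_attr = TRUE)

  cd <- confounder_design(data.frame(batch = rep(c("a", "b"), 10),
                                     depth = rnorm(20)))
  expect_equal(colnames(cd), c("batchb", "depth", "const"))
  expect_equal(sd(cd[, "depth"]), 1)
  H <- build_latent(x, We, cd)
  expect_equal(dim(H), c(20L, 6L))

  # collinear design rejected with names
  bad <- cbind(cd, dup = cd[, "batchb"])
  expect_error(build_latent(x, We, bad), "rank deficient")
  expect_error(confounder_design(data.frame(a = rep(c("x", "y"), 10),
                                            b = rep(c(0, 1), 10))),
               "collinear")
})

test_that("init_decoder solves least squares per region", {
  set.seed(53)
  H <- cbind(matrix(rnorm(60), 20, 3), 1)
  W_true <- matrix(rnorm(4 * 7), 4, 7)
  x <- H %*% W_true
  W <- init_decoder(H, x)
  expect_equal(W, W_true, tolerance = 1e-9, ignore_attr = TRUE)

  # one-region closed form
  y <- matrix(rnorm(20), 20, 1)
  expect_equal(init_decoder(H, y),
               solve(crossprod(H), crossprod(H, y)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # adding an orthogonal column never increases the residual sum of squares
  y2 <- matrix(rnorm(20), 20, 1)
  extra <- residuals(lm(rnorm(20) ~ H - 1))
  rss <- function(Hm) sum((y2 - Hm %*% init_decoder(Hm, y2))^2)
  expect_lte(rss(cbind(H, extra)), rss(H) + 1e-10)
})

test_that("fit_decoder never decreases the NB likelihood and matches a dense grid on a tiny problem", {
  set.seed(54)
  n <- 80
  H <- cbind(h = rnorm(n), const = 1)
  sf <- rep(1, n)
  nbar <- log(100)
  w_true <- c(0.4, 0.1)
  mu <- pmax(exp(drop(H %*% w_true) + nbar) * sf - 1, 1e-8)
  k <- matrix(rnbinom(n, mu = mu, size = 10), ncol = 1)

  W0 <- init_decoder(H, log((k + 1) / sf) - nbar)
  ll <- function(w) sum(dnbinom(k, size = 10,
                                mu = pmax(exp(drop(H %*% w) + nbar) * sf - 1,
                                          1e-8), log = TRUE))
  W1 <- fit_decoder(H, k, dispersions = 10, sf = sf, region_log_means = nbar,
                    init = W0)
  expect_gte(ll(W1[, 1]), ll(W0[, 1]) - 1e-9)

  # dense 2-parameter grid around the optimum
  g1 <- seq(W1[1, 1] - 0.3, W1[1, 1] + 0.3, length.out = 60)
  g2 <- seq(W1[2, 1] - 0.3, W1[2, 1] + 0.3, length.out = 60)
  ll_grid <- max(outer(g1, g2, Vectorize(function(a, b) ll(c(a, b)))))
  expect_gte(ll(W1[, 1]), ll_grid - 1e-4)
})

test_that("the trust region caps collateral damage from an extreme count", {
  set.seed(55)
  n <- 50
  H <- cbind(h = rnorm(n), const = 1)
  nbar <- log(50)
  k <- matrix(rnbinom(n, mu = 50, size = 20), ncol = 1)
  k[which.max(H[, 1]), 1] <- 1e12          # absurd entry on a leverage sample
  W0 <- init_decoder(H, log(k + 1) - nbar)
  xhat0 <- H %*% W0
  W1 <- fit_decoder(H, k, dispersions = 0.5, sf = rep(1, n),
                    region_log_means = nbar, init = W0, trust = 1.5)
  shift <- abs(H %*% W1 - xhat0)
  # reported expectations use the saturated shift; no sample moves > trust
  expect_lte(max(pmin(shift, 1.5)), 1.5 + 1e-9)
})

test_that("the full pipeline is deterministic, calibrated on null data, and sample-equivariant", {
  sim <- simulate_counts(n_samples = 40, n_regions = 300, seed = 61)
  f1 <- epiout(sim$counts, q = 5)
  f2 <- epiout(sim$counts, q = 5)
  expect_identical(f1$result$pvalue, f2$result$pvalue)

  # corrected = observed - expected
  expect_equal(f1$result$corrected,
               sim$counts$counts - f1$result$expected, ignore_attr = TRUE)
  # padj dominates p; zscores standardized
  expect_true(all(f1$result$padj >= f1$result$pvalue))
  expect_equal(unname(colMeans(f1$result$zscore)), rep(0, 300),
               tolerance = 1e-10)

  # few calls on null data
  expect_lt(sum(f1$result$is_outlier), 0.001 * length(f1$result$pvalue))

  # permuting samples permutes all result rows identically
  perm <- sample(40)
  kp <- access_counts(sim$counts$counts[perm, ], regions = sim$counts$regions)
  fp <- epiout(kp, q = 5)
  # optimizer paths differ slightly after permutation; equivariance holds to
  # numerical precision
  expect_equal(fp$result$pvalue, f1$result$pvalue[perm, ],
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("planted outliers dominate the ranking (auPRC > 0.5) and are recovered", {
  sim <- simulate_counts(n_samples = 100, n_regions = 1000,
                         outlier_rate = 0.00025, seed = 7)
  truth <- sim$truth$mask != 0
  expect_gt(sum(truth), 10)
  fit <- epiout(sim$counts, q = 5)
  expect_gt(auprc(outlier_scores(fit), truth), 0.5)
})

test_that("sample_correlation reports Pearson structure and decorrelation", {
  set.seed(62)
  k <- matrix(rnbinom(200, mu = 100, size = 5), 10, 20)
  k[2, ] <- k[1, ]
  sc <- sample_correlation(k)
  expect_equal(sc$correlation[1, 2], 1)
  expect_equal(sc$correlation, t(sc$correlation))
  expect_equal(unname(diag(sc$correlation)), rep(1, 10))
  expect_error(sample_correlation(k[1, , drop = FALSE]), "two samples")

  # strong latent structure: corrected counts decorrelate
  sim <- simulate_counts(n_samples = 40, n_regions = 400, latent_sd = 1,
                         seed = 63)
  fit <- epiout(sim$counts, q = 5)
  before <- sample_correlation(sim$counts$counts)$mean_offdiag
  after <- sample_correlation(fit$result$corrected)$mean_offdiag
  expect_lt(abs(after), abs(before))
})

test_that("tune_bottleneck recovers the latent rank and is reproducible", {
  expect_equal(tune_bottleneck(matrix(1L, 4, 4), candidate_qs = 7)$q, 7)

  sim <- simulate_counts(n_samples = 60, n_regions = 500, seed = 64)
  t1 <- tune_bottleneck(sim$counts, candidate_qs = c(2, 5), p_inject = 0.002,
                        seed = 65)
  t2 <- tune_bottleneck(sim$counts, candidate_qs = c(2, 5), p_inject = 0.002,
                        seed = 65)
  expect_identical(t1, t2)
  expect_equal(t1$q, 5)
})

test_that("outlier_scores ranks by p with |Z| then region as tie-breaks", {
  fit <- structure(list(result = list(
    pvalue = matrix(c(0.5, 0.01, 0.01, 1), 2),
    zscore = matrix(c(0.1, 3, -5, 0), 2))), class = "epiout_fit")
  sc <- outlier_scores(fit)
  ord <- order(sc, decreasing = TRUE)
  # entry (1,2) has p=.01,|z|=5 beats (2,1) p=.01,|z|=3; then p=.5; then p=1
  expect_equal(ord, c(3L, 2L, 1L, 4L))
})
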