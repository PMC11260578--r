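# Negative binomial machinery. Parameterization throughout: size r, mean mu,
# variance mu + mu^2 / r (large r -> Poisson).

nb_loglik <- function(k, mu, r) sum(stats::dnbinom(k, size = r, mu = mu, log = TRUE))

#' Bounded per-region dispersion MLE
#'
#' For each region independently, maximizes the negative binomial
#' log-likelihood of the observed counts given the expected counts over the
#' dispersion `r` within `bounds` (default `[0.01, 1000]`; the bounds guard
#' against numerical instability and overfitting — equidispersed data clamps
#' to the upper bound). Optimization is 1-D Brent search on `log r`, refined
#' against both interval endpoints.
#'
#' @param counts Samples x regions matrix (or `access_counts`).
#' @param expected Matrix of expected counts `khat_ij` (> 0).
#' @param bounds Length-2 numeric, inclusive dispersion bounds.
#' @param exclude Optional logical matrix flagging entries to leave out of
#'   the likelihood (suspected aberrant observations, so that a single
#'   extreme count does not drag a region's dispersion to the lower bound
#'   and mask every other outlier in that region). A region keeps all its
#'   entries if exclusion would leave fewer than three.
#' @return Numeric vector of fitted dispersions, one per region.
#' @export
fit_dispersion <- function(counts, expected, bounds = c(0.01, 1000),
                           exclude = NULL) {
  k <- count_mat(counts)
  mu <- as.matrix(expected)
  stopifnot(all(dim(k) == dim(mu)), all(mu > 0), bounds[1] > 0,
            bounds[2] > bounds[1])
  if (!is.null(exclude)) stopifnot(all(dim(exclude) == dim(k)))
  vapply(seq_len(ncol(k)), function(j) {
    use <- if (is.null(exclude)) rep(TRUE, nrow(k)) else !exclude[, j]
    if (sum(use) < 3L) use <- rep(TRUE, nrow(k))
    f <- function(logr) nb_loglik(k[use, j], mu[use, j], exp(logr))
    if (!is.finite(f(log(bounds[1]))) || !is.finite(f(log(bounds[2]))))
      stop("non-finite negative binomial likelihood for region ", j)
    opt <- stats::optimize(f, interval = log(bounds), maximum = TRUE,
                           tol = 1e-9)
    cand_logr <- c(opt$maximum, log(bounds))
    cand_ll <- c(opt$objective, f(log(bounds[1])), f(log(bounds[2])))
    exp(cand_logr[which.max(cand_ll)])
  }, numeric(1L))
}

#' Two-sided negative binomial test
#'
#' Per (sample, region) entry, the doubled two-sided tail probability of the
#' observed count under NB(mean = expected, dispersion = r_j):
#' `P = 2 * min(1/2, F(k), 1 - F(k - 1))`, capped at 1. With `double = FALSE`
#' the undoubled statistic `min(1/2, F(k), 1 - F(k - 1))` is returned instead
#' (a comparison variant; its maximum is 1/2).
#'
#' @param counts Samples x regions matrix (or `access_counts`).
#' @param expected Matrix of expected counts (> 0).
#' @param dispersions Per-region dispersion vector.
#' @param double Double the smaller tail (default `TRUE`).
#' @param mu_floor Lower floor for the expected count inside the test
#'   (default 0.5 reads): an expectation numerically near zero (the
#'   back-transform floor) must not make a handful of observed reads look
#'   arbitrarily significant.
#' @return Matrix of p-values in (0, 1].
#' @export
nb_pvalues <- function(counts, expected, dispersions, double = TRUE,
                       mu_floor = 0.5) {
  k <- count_mat(counts)
  mu <- pmax(as.matrix(expected), mu_floor)
  stopifnot(all(dim(k) == dim(mu)), length(dispersions) == ncol(k),
            all(mu > 0), all(dispersions > 0))
  r <- matrix(dispersions, nrow(k), ncol(k), byrow = TRUE)
  lower <- stats::pnbinom(k, size = r, mu = mu)
  # survival form: accurate far below double-precision cancellation (~1e-16)
  upper <- stats::pnbinom(k - 1, size = r, mu = mu, lower.tail = FALSE)
  p <- pmin(0.5, lower, upper)
  if (double) p <- pmin(1, 2 * p)
  matrix(p, nrow(k), ncol(k), dimnames = dimnames(k))
}

#' Multiple-testing correction for the outlier test
#'
#' Benjamini-Yekutieli (default) step-up correction applied per sample across
#' regions, i.e. each sample's vector of region-level p-values is corrected
#' independently; `scope = "global"` corrects the whole matrix at once.
#'
#' @param pvalues Samples x regions p-value matrix.
#' @param method Correction method passed to [stats::p.adjust()] (default
#'   `"BY"`).
#' @param scope `"sample"` (per row, default) or `"global"`.
#' @return Matrix of adjusted p-values, `>=` raw elementwise.
#' @export
adjust_pvalues <- function(pvalues, method = "BY",
                           scope = c("sample", "global")) {
  scope <- match.arg(scope)
  p <- as.matrix(pvalues)
  padj <- if (scope == "sample") {
    t(apply(p, 1L, stats::p.adjust, method = method))
  } else {
    matrix(stats::p.adjust(p, method = method), nrow(p), ncol(p))
  }
  dimnames(padj) <- dimnames(p)
  padj
}

#' Log2 fold changes and per-region Z-scores
#'
#' `l_ij = log2((k_ij + 1) / (khat_ij + 1))`; the Z-score standardizes `l`
#' within each region across samples (mean 0, sd 1). Regions with zero
#' fold-change variance get Z = 0 with a warning.
#'
#' @param counts Samples x regions matrix (or `access_counts`).
#' @param expected Matrix of expected counts.
#' @return List with matrices `l2fc` and `zscore`.
#' @export
effect_sizes <- function(counts, expected) {
  k <- count_mat(counts)
  mu <- as.matrix(expected)
  stopifnot(all(dim(k) == dim(mu)))
  l2fc <- log2((k + 1) / (mu + 1))
  mu_l <- colMeans(l2fc)
  sd_l <- apply(l2fc, 2L, stats::sd)
  degenerate <- sd_l == 0 | !is.finite(sd_l)
  if (any(degenerate)) {
    warning(sum(degenerate), " region(s) with zero fold-change variance; Z set to 0")
    sd_l[degenerate] <- 1
  }
  z <- sweep(sweep(l2fc, 2L, mu_l), 2L, sd_l, `/`)
  z[, degenerate] <- 0
  list(l2fc = l2fc, zscore = z)
}

#' Call accessibility outliers
#'
#' A (sample, region) entry is an outlier iff `padj < alpha`, `|l2fc| >
#' min_l2fc`, and either the observed or the expected count is at least
#' `min_count`. Direction is the sign of the fold change.
#'
#' @param padj Adjusted p-value matrix.
#' @param l2fc Log2 fold-change matrix.
#' @param counts Observed counts (matrix or `access_counts`).
#' @param expected Expected counts.
#' @param alpha Significance threshold (default 0.05, strict `<`).
#' @param min_l2fc Minimum absolute log2 fold change (default 0.5, strict `>`).
#' @param min_count Minimum observed-or-expected count (default 50, `>=`).
#' @return List with `is_outlier` (logical matrix) and `direction` (integer
#'   matrix in {-1, 0, +1}).
#' @export
call_outliers <- function(padj, l2fc, counts, expected, alpha = 0.05,
                          min_l2fc = 0.5, min_count = 50) {
  k <- count_mat(counts)
  mu <- as.matrix(expected)
  out <- padj < alpha & abs(l2fc) > min_l2fc &
    (k >= min_count | mu >= min_count)
  list(is_outlier = out,
       direction = ifelse(out, sign(l2fc), 0L))
}
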