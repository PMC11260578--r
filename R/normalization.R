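#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factor: the reference level of each region is
#' its geometric mean across samples; the size factor of a sample is the
#' median over reference regions of count / reference. Regions containing any
#' zero count are excluded from the reference set so all geometric means are
#' positive.
#'
#' @param counts An `access_counts` object or samples x regions matrix.
#' @return Positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(counts) {
  k <- count_mat(counts)
  check_count_matrix(k)
  ref <- colSums(k == 0) == 0L
  if (!any(ref))
    stop("no region with strictly positive counts in every sample; ",
         "loosen filtering before computing size factors")
  logk <- log(k[, ref, drop = FALSE])
  loggeo <- colMeans(logk)                     # per-region geometric mean (log)
  sf <- apply(logk, 1L, function(row) exp(stats::median(row - loggeo)))
  stats::setNames(sf, rownames(k))
}

#' Log-transform and center normalized counts
#'
#' Computes `n_ij = ln((k_ij + 1) / s_i)` and centers each region around zero:
#' `x_ij = n_ij - nbar_j`, where `nbar_j` is the per-region mean of `n_ij`
#' across samples. `x` is the model-scale matrix the autoencoder operates on.
#'
#' @param counts An `access_counts` object or samples x regions matrix.
#' @param sf Size factors; computed with [size_factors()] if missing.
#' @return An object of class `access_norm`: list with `x` (centered matrix),
#'   `region_log_means` (`nbar_j`), `size_factors`.
#' @export
log_normalize <- function(counts, sf = NULL) {
  k <- count_mat(counts)
  check_count_matrix(k)
  if (is.null(sf)) sf <- size_factors(k)
  stopifnot(length(sf) == nrow(k), all(is.finite(sf)), all(sf > 0))
  n <- log(k + 1) - log(sf)                    # ln((k+1)/s_i), s recycled by row
  nbar <- colMeans(n)
  structure(list(x = sweep(n, 2L, nbar), region_log_means = nbar,
                 size_factors = sf),
            class = "access_norm")
}

#' @export
print.access_norm <- function(x, ...) {
  cat(sprintf("access_norm: %d samples x %d regions (centered log scale)\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Back-transform model-scale values to expected counts
#'
#' Inverse of [log_normalize()]: `khat_ij = exp(xhat_ij + nbar_j) * s_i - 1`,
#' floored at a small positive `eps` so the value can serve as a negative
#' binomial mean.
#'
#' @param xhat Samples x regions matrix on the centered log scale.
#' @param region_log_means Per-region `nbar_j` from [log_normalize()].
#' @param sf Per-sample size factors.
#' @param eps Positive floor for the result (default 1e-8).
#' @return Non-negative matrix of expected counts.
#' @export
back_transform <- function(xhat, region_log_means, sf, eps = 1e-8) {
  xhat <- as.matrix(xhat)
  stopifnot(length(region_log_means) == ncol(xhat), length(sf) == nrow(xhat))
  khat <- exp(sweep(xhat, 2L, region_log_means, `+`)) * sf - 1
  pmax(khat, eps)
}
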