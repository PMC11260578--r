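# Artificial-outlier injection benchmark: mask sampling, log-scale
# injection, naive-NB and PCA baselines, precision-recall evaluation.

#' Sample an artificial-outlier mask
#'
#' I.i.d. entries over {-1, 0, +1}: +1 (over-accessibility) with probability
#' `p_inject`, -1 (under-accessibility) with probability `p_inject`, else 0.
#'
#' @param n_samples,n_regions Mask dimensions.
#' @param p_inject Per-direction probability (default 0.0005, i.e. 0.1% of
#'   entries injected in total).
#' @param seed Integer seed; the same seed reproduces the same mask.
#' @return Integer matrix over {-1, 0, +1}.
#' @export
sample_mask <- function(n_samples, n_regions, p_inject = 5e-4, seed = 0L) {
  stopifnot(p_inject >= 0, 2 * p_inject < 1)
  withr_seed(seed, {
    u <- stats::runif(n_samples * n_regions)
    m <- integer(n_samples * n_regions)
    m[u < p_inject] <- 1L
    m[u >= p_inject & u < 2 * p_inject] <- -1L
    matrix(m, n_samples, n_regions)
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Inject artificial outliers on the log scale
#'
#' Shifts masked entries of the centered log-scale matrix by
#' `sigma_j * exp(N(log_amp_mean, log_amp_sd)) * M_ij`, where `sigma_j` is
#' the per-region standard deviation, then back-transforms to the count
#' scale and rounds to the nearest non-negative integer.
#'
#' @param norm An `access_norm` from [log_normalize()].
#' @param mask Mask matrix from [sample_mask()].
#' @param log_amp_mean,log_amp_sd Parameters of the log-normal amplitude
#'   (defaults 3 and 1: amplitudes `exp(N(3, 1))`).
#' @param seed Integer seed for the amplitude draws.
#' @return List with `x` (injected log-scale matrix), `counts` (injected
#'   integer counts) and `amplitudes` (matrix, nonzero at injected entries).
#' @export
inject_outliers <- function(norm, mask, log_amp_mean = 3, log_amp_sd = 1,
                            seed = 0L) {
  stopifnot(inherits(norm, "access_norm"), all(mask %in% c(-1L, 0L, 1L)),
            all(dim(mask) == dim(norm$x)))
  sigma <- apply(norm$x, 2L, stats::sd)
  idx <- which(mask != 0)
  amp <- matrix(0, nrow(mask), ncol(mask))
  if (length(idx))
    amp[idx] <- withr_seed(seed,
      exp(stats::rnorm(length(idx), log_amp_mean, log_amp_sd)))
  shift <- sweep(amp * mask, 2L, sigma, `*`)
  x_inj <- norm$x + shift
  # amplitude draws far in the log-normal tail can overflow the count scale;
  # saturate at the largest exactly representable integer (2^53)
  k_inj <- pmin(round(pmax(back_transform(x_inj, norm$region_log_means,
                                          norm$size_factors, eps = 0), 0)),
                2^53)
  list(x = x_inj, counts = k_inj, amplitudes = amp)
}

#' Naive negative binomial baseline
#'
#' Per region, the NB mean is the plain sample average of the counts (no
#' confounder correction); the dispersion is fitted by the bounded MLE; the
#' two-sided NB test is then applied. The weakest baseline: any latent
#' structure inflates the apparent dispersion.
#'
#' @param counts Samples x regions matrix (or `access_counts`).
#' @return List with `pvalue`, `expected` (constant within region),
#'   `dispersions`.
#' @export
naive_nb_baseline <- function(counts) {
  k <- count_mat(counts)
  check_count_matrix(k)
  expected <- matrix(colMeans(k), nrow(k), ncol(k), byrow = TRUE)
  expected <- pmax(expected, 1e-8)
  disp <- fit_dispersion(k, expected)
  list(pvalue = nb_pvalues(k, expected, disp),
       expected = expected, dispersions = disp)
}

#' PCA baseline
#'
#' Reconstructs the centered log-scale matrix with a rank-`q` PCA
#' projection, back-transforms to expected counts, and scores entries by the
#' absolute per-region Z-score of the log2 fold change. No dispersion, no NB
#' test.
#'
#' @param counts Samples x regions matrix (or `access_counts`).
#' @param q Number of principal components.
#' @return List with `score` (`|Z|` matrix, larger = more outlier-like),
#'   `expected`, `l2fc`.
#' @export
pca_baseline <- function(counts, q) {
  k <- count_mat(counts)
  norm <- log_normalize(k)
  We <- fit_encoder(norm$x, q)
  xhat <- norm$x %*% We %*% t(We)
  expected <- back_transform(xhat, norm$region_log_means, norm$size_factors)
  eff <- suppressWarnings(effect_sizes(k, expected))
  list(score = abs(eff$zscore), expected = expected, l2fc = eff$l2fc)
}

#' Area under the precision-recall curve
#'
#' Interpolation-free (step-wise, average-precision style) auPRC: thresholds
#' are the distinct score values taken from best to worst; at each threshold
#' the precision is weighted by the recall gained there. Ties share a
#' threshold. Matches a brute-force enumeration of every cutoff.
#'
#' @param scores Numeric vector or matrix; larger = more outlier-like.
#' @param labels Logical (or 0/1) vector or matrix of true positives.
#' @return Scalar auPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  s <- as.numeric(scores)
  y <- as.logical(labels)
  stopifnot(length(s) == length(y))
  npos <- sum(y)
  if (npos == 0L) stop("no positive labels")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  grp <- cumsum(!duplicated(s))            # tie groups, best first
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1L, length(y)), grp, sum)
  tp <- cumsum(tp_g)
  n <- cumsum(n_g)
  precision <- tp / n
  recall <- tp / npos
  sum(diff(c(0, recall)) * precision)
}

#' Precision-recall curve
#'
#' @inheritParams auprc
#' @return data.frame with columns `threshold`, `precision`, `recall`.
#' @export
pr_curve <- function(scores, labels) {
  s <- as.numeric(scores)
  y <- as.logical(labels)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  last <- which(!duplicated(s, fromLast = TRUE))   # end of each tie group
  data.frame(threshold = s[last],
             precision = cumsum(y)[last] / last,
             recall = cumsum(y)[last] / sum(y))
}

#' Injection benchmark over repeated masks
#'
#' Repeats the full injection experiment over `n_masks` independently seeded
#' test masks (mask `i` uses seed `seed + i`): inject, run each method on the
#' injected counts, and measure the auPRC of recovering the mask. Also
#' reports precision and recall at the conventional fixed cutoffs
#' (adjusted p < 0.05 for NB-test methods, `|Z| > 2` for PCA).
#'
#' @param counts An `access_counts` or samples x regions matrix (clean
#'   counts; injections are applied internally).
#' @param confounders Optional confounder table / design for the autoencoder.
#' @param q Bottleneck size for `epiout` and the PCA baseline.
#' @param methods Subset of `c("epiout", "pca", "naive")`.
#' @param n_masks Number of test masks (default 10).
#' @param p_inject Per-direction injection probability.
#' @param seed Base seed; mask `i` derives seed `seed + i`.
#' @return An object of class `injection_benchmark`: list with `results`
#'   (data.frame: method, mask, auprc, precision_at_cutoff,
#'   recall_at_cutoff) and `summary` (data.frame: method, mean_auprc,
#'   sd_auprc).
#' @export
benchmark_injection <- function(counts, confounders = NULL, q = 5,
                                methods = c("epiout", "pca", "naive"),
                                n_masks = 10L, p_inject = 5e-4, seed = 0L) {
  methods <- match.arg(methods, several.ok = TRUE)
  k <- count_mat(counts)
  norm <- log_normalize(k)
  rows <- list()
  for (i in seq_len(n_masks)) {
    mask_seed <- seed + i
    mask <- sample_mask(nrow(k), ncol(k), p_inject = p_inject,
                        seed = mask_seed)
    if (!any(mask != 0)) {
      warning("mask ", i, " contains no injected outliers; skipped")
      next
    }
    inj <- inject_outliers(norm, mask, seed = mask_seed)
    truth <- mask != 0
    for (m in methods) {
      if (m == "epiout") {
        fit <- epiout(inj$counts, confounders = confounders, q = q)
        sc <- outlier_scores(fit)
        called <- fit$result$padj < 0.05
      } else if (m == "pca") {
        pb <- pca_baseline(inj$counts, q = q)
        sc <- pb$score
        called <- pb$score > 2
      } else {
        nb <- naive_nb_baseline(inj$counts)
        padj <- adjust_pvalues(nb$pvalue)
        sc <- -nb$pvalue
        called <- padj < 0.05
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, mask = i, auprc = auprc(sc, truth),
        precision_at_cutoff = if (any(called)) sum(called & truth) / sum(called) else NA_real_,
        recall_at_cutoff = sum(called & truth) / sum(truth))
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(auprc ~ method, results,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(method = agg$method,
                        mean_auprc = agg$auprc[, "mean"],
                        sd_auprc = agg$auprc[, "sd"])
  structure(list(results = results, summary = summary),
            class = "injection_benchmark")
}

#' @export
print.injection_benchmark <- function(x, ...) {
  cat("Injection benchmark (mean auPRC over",
      length(unique(x$results$mask)), "masks):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
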