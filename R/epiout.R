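# Linear autoencoder engine: PCA encoder (never trained), least-squares
# decoder initialization, one alternating step of dispersion MLE and
# NB-likelihood decoder fitting.

#' Build a known-confounder design matrix
#'
#' Encodes a covariate table for the latent representation: categorical
#' columns are one-hot encoded with the first level dropped, numeric columns
#' are z-scored (constant numeric columns dropped with a warning), and a
#' constant (intercept) column is always appended. The result must be full
#' column rank.
#'
#' @param meta A data.frame of per-sample covariates, or `NULL` for an
#'   intercept-only design.
#' @param n_samples Number of samples (required when `meta` is `NULL`).
#' @return Numeric matrix, samples x columns, including the constant column.
#' @export
confounder_design <- function(meta = NULL, n_samples = if (!is.null(meta)) nrow(meta)) {
  if (is.null(meta)) {
    stopifnot(!is.null(n_samples))
    return(matrix(1, n_samples, 1L, dimnames = list(NULL, "const")))
  }
  meta <- as.data.frame(meta)
  blocks <- list()
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) {
        warning("dropping constant numeric confounder: ", nm)
        next
      }
      blocks[[nm]] <- matrix((v - mean(v)) / s, ncol = 1L,
                             dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) next
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(nm, levels(f)[-1L])
      blocks[[nm]] <- mm
    }
  }
  design <- cbind(do.call(cbind, blocks), const = 1)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- colnames(design)[setdiff(seq_len(ncol(design)), qrd$pivot[seq_len(qrd$rank)])]
    stop("confounder design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  design
}

#' PCA encoder weights
#'
#' The encoder of the linear autoencoder is fixed to the top-`q` principal
#' axes (right singular vectors) of the centered log-scale matrix; it is
#' never trained further.
#'
#' @param x Samples x regions centered matrix (or an `access_norm`).
#' @param q Bottleneck size, `1 <= q < min(n_samples, n_regions)`.
#' @return Regions x q matrix with orthonormal columns.
#' @export
fit_encoder <- function(x, q) {
  if (inherits(x, "access_norm")) x <- x$x
  x <- as.matrix(x)
  if (q < 1L || q >= min(dim(x)))
    stop("bottleneck q must satisfy 1 <= q < min(n_samples, n_regions)")
  sv <- svd(x, nu = 0L, nv = q)
  sv$v
}

#' Latent representation
#'
#' Projects the data through the encoder and concatenates the known
#' confounder design: `H = [x We | C]`.
#'
#' @param x Samples x regions centered matrix (or `access_norm`).
#' @param encoder_weights Regions x q encoder matrix.
#' @param confounders Confounder design matrix from [confounder_design()];
#'   defaults to intercept-only.
#' @return Samples x (q + c) latent matrix.
#' @export
build_latent <- function(x, encoder_weights, confounders = NULL) {
  if (inherits(x, "access_norm")) x <- x$x
  x <- as.matrix(x)
  if (is.null(confounders)) confounders <- confounder_design(n_samples = nrow(x))
  stopifnot(nrow(confounders) == nrow(x))
  if (qr(confounders)$rank < ncol(confounders))
    stop("confounder design is rank deficient")
  H <- cbind(x %*% encoder_weights, confounders)
  colnames(H) <- c(paste0("latent", seq_len(ncol(encoder_weights))),
                   colnames(confounders))
  H
}

#' Least-squares decoder initialization
#'
#' Ordinary least squares solution of `x ~ H` per region (minimizing
#' `||x - H Wd||^2`); falls back to the pseudoinverse with a warning if the
#' normal equations are singular.
#'
#' @param H Samples x d latent matrix.
#' @param x Samples x regions target matrix (or `access_norm`).
#' @return d x regions decoder weight matrix.
#' @export
init_decoder <- function(H, x) {
  if (inherits(x, "access_norm")) x <- x$x
  x <- as.matrix(x)
  stopifnot(nrow(H) == nrow(x))
  fit <- tryCatch(qr.solve(H, x), error = function(e) {
    warning("singular latent design; using pseudoinverse")
    sv <- svd(H)
    pos <- sv$d > max(dim(H)) * .Machine$double.eps * sv$d[1]
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% x) / sv$d[pos])
  })
  fit <- as.matrix(fit)
  dimnames(fit) <- list(colnames(H), colnames(x))
  fit
}

#' Winsorize a centered log-scale matrix per region
#'
#' Clamps each region's values to `median +/- c * 1.4826 * MAD` (falling back
#' to the standard deviation when the MAD is zero). Used on the model-scale
#' matrix during fitting only: the encoder and decoder estimate latent
#' confounders from the bulk of the data, so a single entry tens of standard
#' deviations away cannot hijack a latent direction; the statistical test is
#' always evaluated on the unclipped observed counts.
#'
#' @param x Samples x regions matrix.
#' @param c Cap in robust standard deviations (default 3); `Inf` disables.
#' @return Clamped matrix.
#' @export
winsorize_xmat <- function(x, c = 3) {
  b <- winsor_bounds(x, c)
  clamp_cols(x, b$lo, b$hi)
}

# Per-region robust bounds median +/- c * 1.4826 * MAD (sd fallback).
winsor_bounds <- function(x, c) {
  if (!is.finite(c))
    return(list(lo = rep(-Inf, ncol(x)), hi = rep(Inf, ncol(x))))
  med <- apply(x, 2L, stats::median)
  scale <- apply(x, 2L, stats::mad)
  zero <- scale == 0
  if (any(zero)) scale[zero] <- apply(x[, zero, drop = FALSE], 2L, stats::sd)
  list(lo = med - c * scale, hi = med + c * scale)
}

clamp_cols <- function(x, lo, hi) {
  pmin(pmax(x, matrix(lo, nrow(x), ncol(x), byrow = TRUE)),
       matrix(hi, nrow(x), ncol(x), byrow = TRUE))
}

# NB negative log-likelihood and gradient for one region's decoder column.
# The per-sample linear-predictor shift relative to the initialization eta0
# saturates at +/- trust natural-log units, so the single likelihood-update
# round cannot move any sample's log expected count arbitrarily far: the
# unbounded NB likelihood gain from chasing a huge observed count (growing
# like the count itself) would otherwise let one aberrant entry drag the
# whole column and collapse every other sample's expectation. With moderate
# shifts the clamp is inactive and the solution is the exact (local) MLE.
# mu_i = max(exp(eta) * s_i - 1, eps); gradient zero where floored/clamped.
decoder_nll <- function(w, H, k, r, s, nbar, eps, eta0 = NULL, trust = Inf) {
  eta <- drop(H %*% w) + nbar
  if (!is.null(eta0)) eta <- eta0 + pmin(pmax(eta - eta0, -trust), trust)
  raw <- exp(eta) * s - 1
  mu <- pmax(raw, eps)
  -sum(stats::dnbinom(k, size = r, mu = mu, log = TRUE))
}

decoder_nll_grad <- function(w, H, k, r, s, nbar, eps, eta0 = NULL,
                             trust = Inf) {
  eta <- drop(H %*% w) + nbar
  active <- rep(TRUE, length(eta))
  if (!is.null(eta0)) {
    delta <- eta - eta0
    active <- abs(delta) < trust
    eta <- eta0 + pmin(pmax(delta, -trust), trust)
  }
  e <- exp(eta) * s
  raw <- e - 1
  mu <- pmax(raw, eps)
  dl_dmu <- k / mu - (k + r) / (mu + r)
  dl_dmu[raw < eps | !active] <- 0
  -drop(crossprod(H, dl_dmu * e))
}

#' Fit the decoder by negative binomial maximum likelihood
#'
#' Per region (an independent problem), updates the decoder column to
#' maximize the NB log-likelihood of the observed counts, with the expected
#' counts obtained by back-transforming `H w` to the count scale. BFGS with
#' analytic gradients, warm-started at `init`; the returned column is
#' guaranteed to have log-likelihood no worse than the initialization.
#'
#' @param H Samples x d latent matrix (fixed).
#' @param counts Samples x regions matrix (or `access_counts`).
#' @param dispersions Per-region dispersion vector.
#' @param sf Per-sample size factors.
#' @param region_log_means Per-region `nbar_j`.
#' @param init d x regions starting weights (from [init_decoder()]).
#' @param eps Expected-count floor (default 1e-8).
#' @param maxit BFGS iteration cap per region (default 100).
#' @param trust Saturation bound, in natural-log units, on how far the
#'   likelihood update may shift any single sample's log expected count away
#'   from the least-squares initialization (default 3, i.e. about a 20-fold
#'   correction). Inactive for well-specified regions, where the result is
#'   the exact (local) NB MLE; on a region containing an extreme count it
#'   caps the collateral damage, since the NB likelihood gain from chasing a
#'   count k grows like k and would otherwise collapse every other sample's
#'   expectation. `Inf` disables the bound.
#' @param xhat_init Optional samples x regions matrix of initial model-scale
#'   predictions to anchor the trust region (defaults to `H %*% init`);
#'   the orchestration passes range-clamped predictions here.
#' @return d x regions fitted decoder weight matrix.
#' @export
fit_decoder <- function(H, counts, dispersions, sf, region_log_means, init,
                        eps = 1e-8, maxit = 100L, trust = 1.5,
                        xhat_init = NULL) {
  k <- count_mat(counts)
  stopifnot(nrow(H) == nrow(k), ncol(init) == ncol(k),
            length(dispersions) == ncol(k),
            length(region_log_means) == ncol(k), length(sf) == nrow(k))
  W <- init
  eta0_all <- if (is.null(xhat_init)) H %*% init else xhat_init
  for (j in seq_len(ncol(k))) {
    w0 <- init[, j]
    eta0 <- eta0_all[, j] + region_log_means[j]
    f0 <- decoder_nll(w0, H, k[, j], dispersions[j], sf,
                      region_log_means[j], eps, eta0 = eta0, trust = trust)
    opt <- tryCatch(
      stats::optim(w0, decoder_nll, decoder_nll_grad, H = H, k = k[, j],
                   r = dispersions[j], s = sf, nbar = region_log_means[j],
                   eps = eps, eta0 = eta0, trust = trust, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) list(par = w0, value = f0))
    if (is.finite(opt$value) && opt$value <= f0) W[, j] <- opt$par
  }
  W
}

#' Run the full outlier-detection pipeline
#'
#' Orchestrates: size factors -> log-normalize -> PCA encoder -> latent
#' representation with known confounders -> least-squares decoder ->
#' dispersion MLE -> NB-likelihood decoder fit -> dispersion re-estimate
#' (one alternating step) -> two-sided NB test -> Benjamini-Yekutieli
#' correction -> effect sizes -> outlier calls -> corrected counts
#' (observed minus expected). Deterministic given its inputs.
#'
#' @param counts An `access_counts` object or samples x regions matrix of
#'   filtered counts.
#' @param confounders Optional data.frame of known per-sample confounders
#'   (see [confounder_design()]), or a ready-made design matrix.
#' @param q Bottleneck size.
#' @param alpha,min_l2fc,min_count Outlier-calling thresholds, see
#'   [call_outliers()].
#' @param padj_method,padj_scope See [adjust_pvalues()].
#' @param winsor_c Robust-sd cap applied to the model-scale matrix during
#'   the provisional first fitting pass (default 3; `Inf` disables all
#'   robustness machinery). See [winsorize_xmat()].
#' @param resid_c Residual cap for the second fitting pass, in robust
#'   residual sds (default 5): entries whose pass-1 residual exceeds this
#'   are treated as suspected aberrations — capped near the model
#'   prediction for fitting and excluded from the dispersion likelihood.
#' @param trust Saturation bound for the decoder likelihood update, in
#'   natural-log units (default 3). See [fit_decoder()].
#' @param eps Expected-count floor.
#' @return An object of class `epiout_fit`: list with `model` (encoder and
#'   decoder weights, latent matrix, bottleneck, dispersions, size factors,
#'   region log-means, confounder design) and `result` (matrices `expected`,
#'   `pvalue`, `padj`, `l2fc`, `zscore`, `is_outlier`, `direction`,
#'   `corrected`).
#' @export
epiout <- function(counts, confounders = NULL, q = 5, alpha = 0.05,
                   min_l2fc = 0.5, min_count = 50, padj_method = "BY",
                   padj_scope = "sample", winsor_c = 3, resid_c = 5, trust = 1.5,
                   eps = 1e-8) {
  k <- count_mat(counts)
  check_count_matrix(k)
  design <- if (is.null(confounders)) {
    confounder_design(n_samples = nrow(k))
  } else if (is.matrix(confounders)) confounders else confounder_design(confounders)

  norm <- log_normalize(k)

  # Pass 1 — provisional fit on marginally winsorized data (cap winsor_c
  # robust sd per region) so no single extreme entry can hijack a latent
  # direction while the residual scale is being established.
  wb <- winsor_bounds(norm$x, winsor_c)
  x1 <- clamp_cols(norm$x, wb$lo, wb$hi)
  We1 <- fit_encoder(x1, q)
  H1 <- build_latent(x1, We1, design)
  xhat1 <- clamp_cols(H1 %*% init_decoder(H1, x1), wb$lo, wb$hi)

  # Pass 2 — flag entries by their pass-1 residual: genuine latent extremes
  # are well predicted (small residual) and are restored unclipped, whereas
  # aberrant entries (huge residual) stay capped near the model prediction
  # and are excluded from the dispersion likelihood.
  res <- norm$x - xhat1
  sres <- apply(res, 2L, stats::mad)
  zero <- sres == 0
  if (any(zero)) sres[zero] <- apply(res[, zero, drop = FALSE], 2L, stats::sd)
  band <- matrix(resid_c * pmax(sres, 1e-8), nrow(res), ncol(res), byrow = TRUE)
  flagged <- abs(res) > band
  x_fit <- pmin(pmax(norm$x, xhat1 - band), xhat1 + band)
  We <- fit_encoder(x_fit, q)
  H <- build_latent(x_fit, We, design)
  Wd0 <- init_decoder(H, x_fit)
  # predictions are interpolations of the cleaned data; never assert an
  # expectation more extreme than the cleaned observations
  rng_lo <- apply(x_fit, 2L, min)
  rng_hi <- apply(x_fit, 2L, max)
  xhat0 <- clamp_cols(H %*% Wd0, rng_lo, rng_hi)
  expected <- back_transform(xhat0, norm$region_log_means,
                             norm$size_factors, eps)
  r0 <- fit_dispersion(k, expected, exclude = flagged)
  Wd <- fit_decoder(H, k, r0, norm$size_factors, norm$region_log_means, Wd0,
                    eps = eps, trust = trust, xhat_init = xhat0)
  # same saturation as inside the decoder objective, so the reported
  # expectations match the fitted likelihood
  xhat <- xhat0 + pmin(pmax(H %*% Wd - xhat0, -trust), trust)
  xhat <- clamp_cols(xhat, rng_lo, rng_hi)
  expected <- back_transform(xhat, norm$region_log_means,
                             norm$size_factors, eps)
  disp <- fit_dispersion(k, expected, exclude = flagged)

  pval <- nb_pvalues(k, expected, disp)
  padj <- adjust_pvalues(pval, method = padj_method, scope = padj_scope)
  eff <- effect_sizes(k, expected)
  calls <- call_outliers(padj, eff$l2fc, k, expected, alpha = alpha,
                         min_l2fc = min_l2fc, min_count = min_count)
  structure(list(
    model = list(encoder_weights = We, decoder_weights = Wd, latent = H,
                 bottleneck = q, dispersions = disp,
                 size_factors = norm$size_factors,
                 region_log_means = norm$region_log_means,
                 confounder_design = design),
    result = list(expected = expected, pvalue = pval, padj = padj,
                  l2fc = eff$l2fc, zscore = eff$zscore,
                  is_outlier = calls$is_outlier, direction = calls$direction,
                  corrected = k - expected)),
    class = "epiout_fit")
}

#' @export
print.epiout_fit <- function(x, ...) {
  cat(sprintf("epiout_fit: %d samples x %d regions, q = %d, %d outlier call(s)\n",
              nrow(x$result$pvalue), ncol(x$result$pvalue),
              x$model$bottleneck, sum(x$result$is_outlier)))
  invisible(x)
}

#' Outlier ranking scores
#'
#' Flattens a fit into a (sample, region) ranking: ascending p-value, ties
#' broken by descending `|Z|`, then by region index (stable, documented).
#' Returned as a numeric score where larger means more outlier-like, suitable
#' for [auprc()].
#'
#' @param fit An `epiout_fit`.
#' @return Matrix of scores, same shape as the p-value matrix.
#' @export
outlier_scores <- function(fit) {
  p <- fit$result$pvalue
  z <- abs(fit$result$zscore)
  n <- length(p)
  ord <- order(p, -z, col(p), row(p))      # best entry first
  sc <- numeric(n)
  sc[ord] <- seq(n, 1L)                    # rank-based score, ties resolved
  matrix(sc, nrow(p), ncol(p), dimnames = dimnames(p))
}

#' Select the bottleneck size by injection-based validation
#'
#' Injects a single validation mask of artificial outliers, runs the full
#' pipeline for every candidate bottleneck, and returns the candidate with
#' the highest validation auPRC. Reproducible given `seed`.
#'
#' @param counts An `access_counts` object or samples x regions matrix.
#' @param confounders Optional confounder table / design.
#' @param candidate_qs Integer vector of candidate bottleneck sizes.
#' @param p_inject Per-direction injection probability (default 5e-4).
#' @param seed Integer seed for the validation mask and amplitudes.
#' @return List with `q` (best candidate) and `auprc` (named vector of
#'   validation auPRC per candidate).
#' @export
tune_bottleneck <- function(counts, confounders = NULL, candidate_qs,
                            p_inject = 5e-4, seed = 0L) {
  stopifnot(length(candidate_qs) >= 1L)
  if (length(candidate_qs) == 1L)
    return(list(q = candidate_qs, auprc = stats::setNames(NA_real_, candidate_qs)))
  k <- count_mat(counts)
  norm <- log_normalize(k)
  mask <- sample_mask(nrow(k), ncol(k), p_inject = p_inject, seed = seed)
  inj <- inject_outliers(norm, mask, seed = seed)
  scores <- vapply(candidate_qs, function(q) {
    fit <- epiout(inj$counts, confounders = confounders, q = q)
    auprc(outlier_scores(fit), mask != 0)
  }, numeric(1L))
  names(scores) <- candidate_qs
  list(q = candidate_qs[which.max(scores)], auprc = scores)
}

#' Cross-correlation between samples
#'
#' Pearson correlation of sample rows, either of raw counts (before
#' correction) or of corrected counts (observed minus expected). Samples with
#' zero variance yield `NA` correlations.
#'
#' @param mat Samples x regions matrix: raw counts or `fit$result$corrected`.
#' @return List with `correlation` (symmetric matrix, unit diagonal) and
#'   `mean_offdiag` (mean off-diagonal value, `NA`s removed).
#' @export
sample_correlation <- function(mat) {
  m <- count_mat(mat)
  if (nrow(m) < 2L) stop("need at least two samples")
  cc <- suppressWarnings(stats::cor(t(m)))
  diag(cc) <- 1
  list(correlation = cc,
       mean_offdiag = mean(cc[lower.tri(cc)], na.rm = TRUE))
}
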