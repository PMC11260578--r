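# Linking accessibility outliers to gene expression outliers: per-gene
# feature construction and ranking evaluation. The downstream boosted
# classifier is an external estimator; this module emits the feature table
# it consumes and evaluates any score column.

#' Label gene expression outliers
#'
#' A (gene, sample) entry is an expression outlier iff `|l2fc| > min_l2fc`
#' and `padj < alpha` (both strict). The engine is count-type agnostic, so
#' the input is simply an `epiout_fit` computed on an expression count
#' matrix.
#'
#' @param fit An `epiout_fit` on expression counts (samples x genes).
#' @param min_l2fc Minimum absolute log2 fold change (default 0.3).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Logical samples x genes matrix.
#' @export
label_expression_outliers <- function(fit, min_l2fc = 0.3, alpha = 0.05) {
  stopifnot(inherits(fit, "epiout_fit"))
  abs(fit$result$l2fc) > min_l2fc & fit$result$padj < alpha
}

#' Per-gene accessibility-outlier features
#'
#' Builds, for every (gene, sample) pair, the predictors used to rank
#' candidate expression outliers: promoter fold change / p-value / outlier
#' status (from the gene's promoter region(s); minimum p and maximum
#' absolute fold change across multiple promoters), the maximum absolute
#' fold change over proximal-enhancer outliers linked to the gene, the
#' maximum absolute fold change over any outlier region within `window` bp
#' of the gene, and the ABC-weighted distal feature
#' `sum over distal enhancers of |ABC * l2fc|`.
#'
#' @param fit An `epiout_fit` on accessibility counts.
#' @param regions `GRanges` of the fitted regions (columns of the fit).
#' @param annotation data.frame from [classify_regions()] for `regions`.
#' @param genes Gene models from [read_gene_models()].
#' @param abc Optional data.frame linking genes to distal enhancers with
#'   columns `gene_id`, `region_id` (distal enhancer), `abc`.
#' @param window Gene vicinity for the windowed feature in bp (default 1e5).
#' @return data.frame with one row per (gene, sample): `gene_id`, `sample`,
#'   `promoter_l2fc`, `promoter_p`, `promoter_is_outlier`,
#'   `proximal_max_abs_l2fc`, `window_max_abs_l2fc`, `distal_abc_weighted`.
#'   Promoter features are `NA` for genes without a promoter region; the
#'   rows are retained.
#' @export
build_gene_features <- function(fit, regions, annotation, genes, abc = NULL,
                                window = 1e5) {
  stopifnot(inherits(fit, "epiout_fit"))
  regions <- as_granges(regions)
  stopifnot(length(regions) == ncol(fit$result$l2fc),
            nrow(annotation) == length(regions))
  samples <- rownames(fit$result$l2fc)
  if (is.null(samples)) samples <- sprintf("sample_%02d", seq_len(nrow(fit$result$l2fc)))
  gene_ids <- genes$genes$gene_id
  region_id <- annotation$region_id

  linked <- strsplit(annotation$genes, ",", fixed = TRUE)
  link_df <- data.frame(
    region = rep(seq_along(regions), lengths(linked)),
    gene_id = unlist(linked), stringsAsFactors = FALSE)
  link_df <- link_df[nzchar(link_df$gene_id), , drop = FALSE]

  prom <- link_df[annotation$class[link_df$region] == "promoter", , drop = FALSE]
  prox <- link_df[annotation$locality[link_df$region] == "proximal", , drop = FALSE]

  gwin <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes$genes),
    IRanges::IRanges(pmax(GenomicRanges::start(genes$genes) - window, 1L),
                     GenomicRanges::end(genes$genes) + window))
  win_hits <- GenomicRanges::findOverlaps(gwin, regions, ignore.strand = TRUE)

  l2fc <- fit$result$l2fc; pval <- fit$result$pvalue
  padj <- fit$result$padj; out <- fit$result$is_outlier

  rows <- vector("list", length(gene_ids))
  for (gi in seq_along(gene_ids)) {
    g <- gene_ids[gi]
    pr <- prom$region[prom$gene_id == g]
    px <- prox$region[prox$gene_id == g]
    wr <- S4Vectors::subjectHits(win_hits)[S4Vectors::queryHits(win_hits) == gi]
    ab <- if (!is.null(abc)) abc[abc$gene_id == g, , drop = FALSE] else NULL
    ar <- if (!is.null(ab) && nrow(ab)) match(ab$region_id, region_id) else integer()

    promoter_l2fc <- promoter_p <- rep(NA_real_, length(samples))
    promoter_out <- rep(NA, length(samples))
    if (length(pr)) {
      pl <- l2fc[, pr, drop = FALSE]
      promoter_l2fc <- pl[cbind(seq_along(samples),
                                max.col(abs(pl), ties.method = "first"))]
      promoter_p <- apply(pval[, pr, drop = FALSE], 1L, min)
      promoter_out <- apply(out[, pr, drop = FALSE], 1L, any)
    }
    feat_max <- function(cols) {
      if (!length(cols)) return(numeric(length(samples)))
      m <- abs(l2fc[, cols, drop = FALSE]) * out[, cols, drop = FALSE]
      apply(m, 1L, max)
    }
    distal <- if (length(ar)) {
      ok <- !is.na(ar)
      as.numeric(abs(l2fc[, ar[ok], drop = FALSE]) %*% abs(ab$abc[ok]))
    } else numeric(length(samples))

    rows[[gi]] <- data.frame(
      gene_id = g, sample = samples,
      promoter_l2fc = promoter_l2fc, promoter_p = promoter_p,
      promoter_is_outlier = promoter_out,
      proximal_max_abs_l2fc = feat_max(px),
      window_max_abs_l2fc = feat_max(wr),
      distal_abc_weighted = distal,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Rank (gene, sample) pairs by a feature and evaluate against labels
#'
#' Ranks every (gene, sample) pair by the chosen feature (larger = more
#' likely an expression outlier; `promoter` uses `|promoter_l2fc|`,
#' `combined` uses an externally supplied `score` column) and evaluates the
#' ranking against expression-outlier labels with the shared
#' precision-recall engine ([auprc()]).
#'
#' @param features Feature table from [build_gene_features()], optionally
#'   with a `score` column for `ranking = "combined"`.
#' @param labels data.frame with columns `gene_id`, `sample`, `label`
#'   (logical), or a logical samples x genes matrix with dimnames.
#' @param ranking One of `"promoter"`, `"proximal"`, `"window"`, `"distal"`,
#'   `"combined"`.
#' @return List with `auprc`, `prevalence`, and `curve` (from [pr_curve()]).
#' @export
rank_and_evaluate <- function(features, labels,
                              ranking = c("promoter", "proximal", "window",
                                          "distal", "combined")) {
  ranking <- match.arg(ranking)
  score <- switch(ranking,
    promoter = abs(features$promoter_l2fc),
    proximal = features$proximal_max_abs_l2fc,
    window = features$window_max_abs_l2fc,
    distal = features$distal_abc_weighted,
    combined = {
      if (!"score" %in% names(features))
        stop("ranking = 'combined' needs a `score` column from an external model")
      features$score
    })
  score[is.na(score)] <- 0
  if (is.matrix(labels)) {
    idx <- cbind(match(features$sample, rownames(labels)),
                 match(features$gene_id, colnames(labels)))
    y <- labels[idx]
  } else {
    key <- paste(labels$gene_id, labels$sample)
    y <- labels$label[match(paste(features$gene_id, features$sample), key)]
  }
  y[is.na(y)] <- FALSE
  if (!any(y)) stop("no positive labels")
  list(auprc = auprc(score, y), prevalence = mean(y),
       curve = pr_curve(score, y))
}
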