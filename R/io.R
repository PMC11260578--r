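# Plain-text I/O: counts as TSV (regions as rows `chrom:start-end`, samples
# as columns), size factors, and the flat outlier table.

#' Write a count matrix as TSV
#'
#' Regions as rows (id `chrom:start-end`, BED coordinates), samples as
#' columns.
#'
#' @param counts An `access_counts` object.
#' @param file Output path.
#' @export
write_counts_tsv <- function(counts, file) {
  stopifnot(inherits(counts, "access_counts"))
  m <- t(counts$counts)
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a count matrix from TSV
#'
#' Inverse of [write_counts_tsv()]; region ids `chrom:start-end` are parsed
#' back into coordinates.
#'
#' @param file TSV path.
#' @return An [access_counts()] object.
#' @export
read_counts_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1L]]
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(m) <- ids
  parts <- regmatches(ids, regexec("^(.+):(\\d+)-(\\d+)$", ids))
  regions <- NULL
  if (all(lengths(parts) == 4L)) {
    regions <- GenomicRanges::GRanges(
      vapply(parts, `[`, character(1L), 2L),
      IRanges::IRanges(as.integer(vapply(parts, `[`, character(1L), 3L)) + 1L,
                       as.integer(vapply(parts, `[`, character(1L), 4L))))
  }
  access_counts(m, regions = regions)
}

#' Write per-sample size factors as a two-column TSV
#' @param sf Named numeric vector from [size_factors()].
#' @param file Output path.
#' @export
write_size_factors <- function(sf, file) {
  utils::write.table(
    data.frame(sample = names(sf), size_factor = unname(sf)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Flat table of called outliers
#'
#' One row per flagged (sample, region) pair: direction, p-value, adjusted
#' p-value, log2 fold change, Z-score, observed and expected counts.
#'
#' @param fit An `epiout_fit`.
#' @param counts The counts the fit was computed on (matrix or
#'   `access_counts`).
#' @param file Optional TSV path; when given, the table is also written.
#' @return data.frame (invisibly when `file` is given).
#' @export
outlier_table <- function(fit, counts, file = NULL) {
  stopifnot(inherits(fit, "epiout_fit"))
  k <- count_mat(counts)
  idx <- which(fit$result$is_outlier, arr.ind = TRUE)
  res <- fit$result
  df <- data.frame(
    sample = rownames(k)[idx[, 1L]],
    region = colnames(k)[idx[, 2L]],
    direction = ifelse(res$direction[idx] > 0, "over", "under"),
    pvalue = res$pvalue[idx], padj = res$padj[idx],
    l2fc = res$l2fc[idx], zscore = res$zscore[idx],
    observed = k[idx], expected = res$expected[idx],
    stringsAsFactors = FALSE)
  df <- df[order(df$pvalue), , drop = FALSE]
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Read peaks from a BED3+/narrowPeak file
#'
#' Only the first three columns are used; extra columns are ignored.
#'
#' @param file BED path.
#' @return `GRanges`.
#' @export
read_peaks_bed <- function(file) {
  df <- utils::read.table(file, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  as_granges(df)
}
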