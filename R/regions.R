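#' Merge peaks closer than a minimum gap
#'
#' Collapses any two same-chromosome intervals whose gap (next start minus
#' previous end, BED 0-based half-open coordinates) is strictly smaller than
#' `min_gap`. The resulting peak set is sorted, non-overlapping, and every
#' adjacent same-chromosome pair is separated by at least `min_gap` bp, which
#' is the precondition of the sorted-sweep read counter: together with the
#' assumption that `min_gap` exceeds the read length it guarantees a read can
#' overlap at most one peak.
#'
#' @param regions A `GRanges`, or a data.frame with columns `chrom`, `start`,
#'   `end` in BED convention (0-based half-open).
#' @param min_gap Minimum gap in bp (default 200). A gap exactly equal to
#'   `min_gap` is NOT merged (strict inequality).
#' @return A sorted `GRanges` of merged peaks.
#' @examples
#' merge_close_regions(data.frame(chrom = "chr1",
#'                                start = c(100, 350),
#'                                end   = c(300, 500)))
#' @export
merge_close_regions <- function(regions, min_gap = 200) {
  stopifnot(is.numeric(min_gap), length(min_gap) == 1L, min_gap >= 0)
  gr <- as_granges(regions)
  if (length(gr) == 0L) return(gr)
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr), ignore.strand = TRUE)
  # reduce() merges ranges separated by a gap < min.gapwidth: exactly the
  # strict-inequality tie-break wanted here (gap == min_gap stays split).
  GenomicRanges::reduce(gr, min.gapwidth = min_gap, ignore.strand = TRUE)
}

# Accept GRanges or BED-convention data.frame; validate intervals.
as_granges <- function(regions) {
  if (methods::is(regions, "GRanges")) return(granges_validate(regions))
  if (is.data.frame(regions)) {
    cols <- c("chrom", "start", "end")
    if (!all(cols %in% names(regions)))
      stop("region table must have columns chrom, start, end")
    bad <- which(regions$start >= regions$end | regions$start < 0)
    if (length(bad))
      stop("malformed interval (start >= end or negative) at record(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    if (nrow(regions) == 0L) return(GenomicRanges::GRanges())
    # BED 0-based half-open -> GRanges 1-based closed
    return(GenomicRanges::GRanges(regions$chrom,
                                  IRanges::IRanges(regions$start + 1L, regions$end)))
  }
  stop("regions must be a GRanges or a chrom/start/end data.frame")
}

granges_validate <- function(gr) {
  if (any(GenomicRanges::width(gr) < 1L))
    stop("malformed interval (zero or negative width) at record(s): ",
         paste(utils::head(which(GenomicRanges::width(gr) < 1L), 5L), collapse = ", "))
  gr
}

#' Region identifiers in `chrom:start-end` form (BED coordinates)
#' @param regions A `GRanges`.
#' @return Character vector of ids.
#' @export
region_ids <- function(regions) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(regions)),
          GenomicRanges::start(regions) - 1L, GenomicRanges::end(regions))
}

#' Container for a samples x regions accessibility count matrix
#'
#' Thin S3 wrapper keeping the integer count matrix (rows = samples, columns =
#' regions) aligned with the peak coordinates and optional sample metadata.
#'
#' @param counts Integer matrix, samples x regions, all entries >= 0.
#' @param regions `GRanges` of length `ncol(counts)`, or `NULL`.
#' @param sample_meta Optional data.frame of per-sample covariates.
#' @return An object of class `access_counts` with elements `counts`,
#'   `regions`, `sample_meta`.
#' @export
access_counts <- function(counts, regions = NULL, sample_meta = NULL) {
  counts <- as.matrix(counts)
  check_count_matrix(counts)
  if (!is.null(regions)) {
    regions <- as_granges(regions)
    if (length(regions) != ncol(counts))
      stop("length(regions) must equal ncol(counts)")
    if (is.null(colnames(counts))) colnames(counts) <- region_ids(regions)
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("sample_%02d", seq_len(nrow(counts)))
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != nrow(counts))
      stop("sample_meta rows must match samples")
  }
  structure(list(counts = counts, regions = regions, sample_meta = sample_meta),
            class = "access_counts")
}

#' @export
print.access_counts <- function(x, ...) {
  cat(sprintf("access_counts: %d samples x %d regions\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$regions))
    cat("  regions:", paste(utils::head(region_ids(x$regions), 3L), collapse = ", "),
        if (length(x$regions) > 3L) "..." else "", "\n")
  invisible(x)
}

check_count_matrix <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  invisible(TRUE)
}

count_mat <- function(counts) {
  if (inherits(counts, "access_counts")) counts$counts else as.matrix(counts)
}

#' Filter regions by replication rate
#'
#' Keeps a region only if (i) at least one sample reaches `high_count` reads
#' and (ii) at least `min_fraction` of samples have at least `min_reads`
#' reads. Both thresholds are inclusive (`>=`).
#'
#' @param counts An `access_counts` object or samples x regions matrix.
#' @param high_count Minimum of the per-region maximum count (default 100).
#' @param min_reads Minimum supporting reads per sample (default 2).
#' @param min_fraction Minimum fraction of samples with `min_reads` (default 0.5).
#' @return List with `counts` (filtered, same class as input) and `keep`
#'   (logical mask over regions).
#' @export
filter_regions <- function(counts, high_count = 100, min_reads = 2,
                           min_fraction = 0.5) {
  k <- count_mat(counts)
  check_count_matrix(k)
  if (length(k) == 0L) stop("counts must be non-empty")
  keep <- apply(k, 2L, max) >= high_count &
    colMeans(k >= min_reads) >= min_fraction
  filtered <- if (inherits(counts, "access_counts")) {
    access_counts(k[, keep, drop = FALSE],
                  regions = if (!is.null(counts$regions)) counts$regions[keep],
                  sample_meta = counts$sample_meta)
  } else {
    k[, keep, drop = FALSE]
  }
  list(counts = filtered, keep = unname(keep))
}
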