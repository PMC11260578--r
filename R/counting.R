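#' Sorted-sweep overlap counter
#'
#' Core of the read counter: given reads and peaks on one chromosome, both
#' sorted by start coordinate (1-based closed intervals), counts for every
#' peak the number of reads overlapping it by at least 1 bp in a single pass
#' (two stacks, two pointers; O(r + p) time, O(p) memory). Assumes peaks are
#' non-overlapping and separated by more than a read length, so a read
#' overlaps at most one peak; reads violating that assumption are assigned to
#' the first overlapping peak and counted in `n_spanning`.
#'
#' @param read_start,read_end Integer vectors, sorted by `read_start`.
#' @param peak_start,peak_end Integer vectors, sorted, non-overlapping.
#' @return List with `counts` (integer, one per peak) and `n_spanning`
#'   (number of reads that overlapped more than one peak).
#' @export
sweep_overlap_counts <- function(read_start, read_end, peak_start, peak_end) {
  np <- length(peak_start)
  nr <- length(read_start)
  counts <- integer(np)
  n_spanning <- 0L
  if (np == 0L || nr == 0L)
    return(list(counts = counts, n_spanning = n_spanning))
  if (is.unsorted(read_start)) stop("reads must be sorted by start")
  if (is.unsorted(peak_start)) stop("peaks must be sorted by start")
  j <- 1L
  for (i in seq_len(nr)) {
    rs <- read_start[i]; re <- read_end[i]
    # pop peaks that end strictly before this (and all later) reads
    while (j <= np && peak_end[j] < rs) j <- j + 1L
    if (j > np) break
    if (peak_start[j] <= re) {            # >= 1 bp overlap
      counts[j] <- counts[j] + 1L
      if (j < np && peak_start[j + 1L] <= re)
        n_spanning <- n_spanning + 1L     # gap assumption violated
    }
  }
  list(counts = counts, n_spanning = n_spanning)
}

# Reference-consumed width of a CIGAR string (ops M, D, N, =, X).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    m <- gregexpr("(\\d+)([MIDNSHP=X])", cg)[[1]]
    lens <- as.integer(substr(rep(cg, length(m)), m,
                              m + attr(m, "match.length") - 2L))
    ops <- substr(rep(cg, length(m)), m + attr(m, "match.length") - 1L,
                  m + attr(m, "match.length") - 1L)
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1L), USE.NAMES = FALSE)
}

#' Count aligned reads per peak from a BAM file
#'
#' Streams a coordinate-sorted, indexed BAM one chromosome at a time and
#' counts, for every peak, the reads whose aligned reference span (CIGAR
#' consumed length) overlaps the peak by at least 1 bp, using the
#' sorted-sweep algorithm. Peaks must first be merged with
#' [merge_close_regions()] so that no read can overlap two peaks.
#'
#' @param bam_file Path to an indexed, coordinate-sorted BAM.
#' @param peaks `GRanges` of merged peaks.
#' @param min_mapq Minimum mapping quality (default 10); reads below are
#'   skipped.
#' @param drop_duplicates Drop reads flagged as PCR/optical duplicates
#'   (default `FALSE`: duplicates are retained).
#' @return Integer vector of counts, one per peak, named by region id. A
#'   warning is emitted if any read overlapped more than one peak
#'   (gap-assumption violation).
#' @export
count_reads <- function(bam_file, peaks, min_mapq = 10, drop_duplicates = FALSE) {
  peaks <- as_granges(peaks)
  hdr <- Rsamtools::scanBamHeader(bam_file)[[1L]]
  so <- grep("^SO:", unlist(hdr$text[names(hdr$text) == "@HD"]), value = TRUE)
  if (!length(so) || !grepl("coordinate", so))
    stop("BAM must be coordinate-sorted: ", bam_file)
  targets <- hdr$targets
  counts <- integer(length(peaks))
  n_spanning <- 0L
  for (chrom in unique(as.character(GenomicRanges::seqnames(peaks)))) {
    idx <- which(as.character(GenomicRanges::seqnames(peaks)) == chrom)
    idx <- idx[order(GenomicRanges::start(peaks)[idx])]
    if (!chrom %in% names(targets)) {
      warning("chromosome ", chrom, " absent from BAM header; zero counts")
      next
    }
    flags <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isDuplicate = if (drop_duplicates) FALSE else NA)
    param <- Rsamtools::ScanBamParam(
      flag = flags, what = c("pos", "cigar", "mapq"),
      which = GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, targets[[chrom]])))
    rec <- Rsamtools::scanBam(bam_file, param = param)[[1L]]
    keep <- !is.na(rec$pos) & !is.na(rec$mapq) & rec$mapq >= min_mapq
    rs <- rec$pos[keep]
    re <- rs + cigar_ref_width(rec$cigar[keep]) - 1L
    ord <- order(rs)
    res <- sweep_overlap_counts(rs[ord], re[ord],
                                GenomicRanges::start(peaks)[idx],
                                GenomicRanges::end(peaks)[idx])
    counts[idx] <- res$counts
    n_spanning <- n_spanning + res$n_spanning
  }
  if (n_spanning > 0L)
    warning(n_spanning, " read(s) overlapped more than one peak; ",
            "assigned to the first peak. Re-merge peaks with a larger min_gap.")
  names(counts) <- region_ids(peaks)
  counts
}

#' Build a samples x regions count matrix from BAM files
#'
#' @param bam_files Character vector of indexed BAM paths; names become
#'   sample ids (defaults to file basenames).
#' @param peaks `GRanges` of merged peaks.
#' @param ... Passed to [count_reads()].
#' @return An [access_counts()] object.
#' @export
count_matrix <- function(bam_files, peaks, ...) {
  peaks <- as_granges(peaks)
  ids <- names(bam_files)
  if (is.null(ids)) ids <- sub("\\.bam$", "", basename(bam_files))
  k <- t(vapply(bam_files, function(b) as.integer(count_reads(b, peaks, ...)),
                integer(length(peaks))))
  rownames(k) <- ids
  access_counts(k, regions = peaks)
}
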