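# Shared test utilities: brute-force oracles and random fixture builders.
# All randomness is seeded by the caller.

# All-pairs interval overlap oracle (1-based closed coordinates).
brute_force_counts <- function(read_start, read_end, read_chrom,
                               peak_start, peak_end, peak_chrom) {
  vapply(seq_along(peak_start), function(j) {
    sum(read_chrom == peak_chrom[j] &
          read_start <= peak_end[j] & read_end >= peak_start[j])
  }, integer(1L))
}

# Random merged peak set on 1-2 chromosomes (GRanges, gaps > min_gap).
random_peaks <- function(n_peaks, chroms = c("chr1", "chr2"), min_gap = 300L,
                         max_width = 400L) {
  chrom <- sort(sample(chroms, n_peaks, replace = TRUE))
  starts <- integer(n_peaks)
  ends <- integer(n_peaks)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos <- 1000L
    for (i in idx) {
      starts[i] <- pos
      ends[i] <- pos + sample.int(max_width, 1L) + 50L
      pos <- ends[i] + min_gap + sample.int(500L, 1L)
    }
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
}

# Random reads (1-based closed spans) scattered over and around peaks.
random_reads <- function(n_reads, peaks, read_len = 100L) {
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  span_max <- max(GenomicRanges::end(peaks)) + 2L * read_len
  chrom <- sample(unique(chroms), n_reads, replace = TRUE)
  start <- sample.int(span_max, n_reads, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + read_len - 1L)
}

# Reference step-up BY adjustment on one vector (independent oracle).
by_stepup <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force average-precision: enumerate every distinct threshold.
brute_force_auprc <- function(scores, labels) {
  s <- as.numeric(scores)
  y <- as.logical(labels)
  th <- sort(unique(s), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  npos <- sum(y)
  for (t in th) {
    sel <- s >= t
    prec <- sum(y & sel) / sum(sel)
    rec <- sum(y & sel) / npos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}
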