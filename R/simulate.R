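# Synthetic fixture generators. Everything the package consumes — count
# matrices with latent structure, alignments, gene models, histone marks,
# Hi-C contacts — can be produced here deterministically, so the full test
# suite runs offline with truth tables for parameter recovery.

#' Simulate an accessibility count matrix with latent structure
#'
#' Generative model mirroring the fitted one: a rank-`q_true` latent block on
#' the centered log scale plus optional batch effects, per-region log-means,
#' per-sample size factors, and negative binomial sampling with per-region
#' dispersions. Optionally plants ground-truth outliers by shifting entries
#' on the log scale by `sigma_j * exp(N(log_amp_mean, log_amp_sd)) * M_ij`
#' before sampling. Defaults describe a mid-sized ATAC cohort: strong shared
#' latent variation (raw sample-sample correlations near 0.9), region means
#' between 50 and 500 reads (the replication filter's regime), moderate
#' overdispersion.
#'
#' @param n_samples,n_regions Matrix dimensions (defaults 100 x 1000).
#' @param q_true Latent rank (default 5).
#' @param latent_sd Standard deviation of the latent loadings per factor
#'   (default 0.5, natural-log scale).
#' @param mean_range Range of per-region mean counts (default c(50, 500),
#'   log-uniform).
#' @param dispersion_range Range of per-region NB dispersions (default
#'   c(2, 100), log-uniform).
#' @param size_factor_range Range of per-sample size factors (default
#'   c(2/3, 1.5), log-uniform).
#' @param n_batches Number of batch levels for an optional categorical
#'   confounder (0 = none).
#' @param batch_sd Standard deviation of per-(batch, region) effects.
#' @param outlier_rate Per-direction plant probability (default 0).
#' @param log_amp_mean,log_amp_sd Plant amplitude distribution (defaults 3, 1).
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return List with `counts` (an [access_counts()] with regions and, when
#'   batches are simulated, `sample_meta$batch`) and `truth` (mask,
#'   amplitudes, dispersions, size factors, region log-means, latent factors
#'   and loadings, `q_true`).
#' @export
simulate_counts <- function(n_samples = 100, n_regions = 1000, q_true = 5,
                            latent_sd = 0.5, mean_range = c(50, 500),
                            dispersion_range = c(2, 100),
                            size_factor_range = c(2 / 3, 1.5),
                            n_batches = 0, batch_sd = 0.5,
                            outlier_rate = 0, log_amp_mean = 3,
                            log_amp_sd = 1, seed = 0L) {
  withr_seed(seed, {
    H <- matrix(stats::rnorm(n_samples * q_true), n_samples, q_true)
    W <- matrix(stats::rnorm(q_true * n_regions, sd = latent_sd), q_true,
                n_regions)
    x <- H %*% W
    meta <- NULL
    if (n_batches >= 2) {
      batch <- factor(sample(seq_len(n_batches), n_samples, replace = TRUE))
      eff <- matrix(stats::rnorm(n_batches * n_regions, sd = batch_sd),
                    n_batches, n_regions)
      x <- x + eff[as.integer(batch), , drop = FALSE]
      meta <- data.frame(batch = batch)
    }
    nbar <- log(exp(stats::runif(n_regions, log(mean_range[1]),
                                 log(mean_range[2]))))
    sf <- exp(stats::runif(n_samples, log(size_factor_range[1]),
                           log(size_factor_range[2])))
    r <- exp(stats::runif(n_regions, log(dispersion_range[1]),
                          log(dispersion_range[2])))
    mask <- matrix(0L, n_samples, n_regions)
    amp <- matrix(0, n_samples, n_regions)
    if (outlier_rate > 0) {
      u <- stats::runif(n_samples * n_regions)
      mask[u < outlier_rate] <- 1L
      mask[u >= outlier_rate & u < 2 * outlier_rate] <- -1L
      idx <- which(mask != 0)
      amp[idx] <- exp(stats::rnorm(length(idx), log_amp_mean, log_amp_sd))
      sigma <- apply(x, 2L, stats::sd)
      x <- x + sweep(amp * mask, 2L, sigma, `*`)
    }
    mu <- pmax(exp(sweep(x, 2L, nbar, `+`)) * sf - 1, 1e-8)
    k <- matrix(stats::rnbinom(n_samples * n_regions,
                               size = rep(r, each = n_samples), mu = mu),
                n_samples, n_regions)
    regions <- tile_regions(n_regions)
    list(counts = access_counts(k, regions = regions, sample_meta = meta),
         truth = list(mask = mask, amplitudes = amp, dispersions = r,
                      size_factors = sf, region_log_means = nbar,
                      latent = H, loadings = W, q_true = q_true, x = x))
  })
}

# Evenly spaced 500-bp peaks (2,500-bp spacing) over two ~1-Mb chromosomes.
tile_regions <- function(n_regions, width = 500L, spacing = 2500L) {
  half <- ceiling(n_regions / 2)
  per_chrom <- c(half, n_regions - half)
  chrom <- rep(paste0("chr", seq_along(per_chrom)), per_chrom)
  start <- unlist(lapply(per_chrom, function(n)
    1000L + spacing * (seq_len(n) - 1L)))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width))
}

#' Write a synthetic indexed BAM with exact per-peak depths
#'
#' Generates, for each peak, the requested number of well-mapped reads
#' (every read overlaps its peak by at least 1 bp and no other peak), plus
#' optional low-MAPQ reads over peaks (excluded at the default filter) and
#' background reads placed in inter-peak gaps. The SAM is converted to a
#' coordinate-sorted, indexed BAM via Rsamtools.
#'
#' @param peaks `GRanges` of merged peaks.
#' @param depths Integer vector of requested counts, one per peak.
#' @param read_len Read length in bp (default 100; must be below the merge
#'   gap).
#' @param n_low_mapq Low-quality (MAPQ 5) reads to scatter over random peaks.
#' @param n_background Reads placed strictly outside every peak.
#' @param seed Integer seed.
#' @param dir Output directory (default `tempdir()`).
#' @param prefix File name prefix.
#' @return List with `bam` (path), `bed` (path to the peak BED), and
#'   `peaks`.
#' @export
simulate_alignment_fixture <- function(peaks, depths, read_len = 100L,
                                       n_low_mapq = 0L, n_background = 0L,
                                       seed = 0L, dir = tempdir(),
                                       prefix = "synthetic") {
  peaks <- as_granges(peaks)
  stopifnot(length(depths) == length(peaks), all(depths >= 0))
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  chrom_len <- vapply(split(GenomicRanges::end(peaks), chroms), max,
                      numeric(1L)) + 10L * read_len

  withr_seed(seed, {
    recs <- list()
    add_read <- function(chrom, pos, mapq, id) {
      recs[[length(recs) + 1L]] <<- data.frame(
        qname = id, flag = 0L, rname = chrom, pos = pos, mapq = mapq,
        cigar = paste0(read_len, "M"), stringsAsFactors = FALSE)
    }
    for (j in seq_along(peaks)) {
      if (depths[j] == 0L) next
      lo <- max(GenomicRanges::start(peaks)[j] - read_len + 1L, 1L)
      hi <- GenomicRanges::end(peaks)[j]
      pos <- sample(seq(lo, hi), depths[j], replace = TRUE)
      for (p in pos) add_read(chroms[j], p, 60L,
                              sprintf("read_p%d_%d", j, p))
    }
    if (n_low_mapq > 0L) {
      js <- sample(seq_along(peaks), n_low_mapq, replace = TRUE)
      for (j in js) add_read(chroms[j], GenomicRanges::start(peaks)[j], 5L,
                             sprintf("lowq_%d", j))
    }
    if (n_background > 0L) {
      for (b in seq_len(n_background)) {
        chrom <- sample(names(chrom_len), 1L)
        on_chrom <- peaks[chroms == chrom]
        repeat {
          pos <- sample.int(as.integer(chrom_len[[chrom]] - read_len), 1L)
          cand <- GenomicRanges::GRanges(chrom,
                                         IRanges::IRanges(pos, width = read_len))
          if (!any(IRanges::overlapsAny(cand, on_chrom))) break
        }
        add_read(chrom, pos, 60L, sprintf("bg_%d", b))
      }
    }
    sam <- file.path(dir, paste0(prefix, ".sam"))
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len),
                        as.integer(chrom_len)))
    body <- character()
    if (length(recs)) {
      df <- do.call(rbind, recs)
      df <- df[order(df$rname, df$pos), , drop = FALSE]
      body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                      df$qname, df$flag, df$rname, df$pos, df$mapq, df$cigar,
                      strrep("A", read_len))
    }
    writeLines(c(header, body), sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, prefix), overwrite = TRUE,
                            indexDestination = TRUE)
    bed <- file.path(dir, paste0(prefix, "_peaks.bed"))
    utils::write.table(
      data.frame(chroms, GenomicRanges::start(peaks) - 1L,
                 GenomicRanges::end(peaks)),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    list(bam = bam, bed = bed, peaks = peaks)
  })
}

#' Generate a toy annotation fixture: GTF, histone marks, Hi-C contacts
#'
#' A two-gene toy genome engineered so every region class is realised: a
#' promoter at each gene's TSS (H3K4me3), an active proximal enhancer inside
#' a gene body (H3K4me1 + H3K27ac), a poised distal enhancer (H3K4me1
#' only), an active distal enhancer, and an unannotated region. Hi-C
#' contacts between all peak-pair bins follow an exact power law
#' `score = scale * distance^exponent` so the distance regression can be
#' validated against the planted exponent.
#'
#' @param seed Integer seed (placement jitter only; classes are fixed by
#'   construction).
#' @param dir Output directory (default `tempdir()`).
#' @param exponent,scale Planted power-law parameters (defaults -1, 1e6).
#' @return List with paths `gtf`, `marks` (named BED paths), `contacts`
#'   (TSV path), plus the objects: `peaks` (`GRanges`), `mark_ranges`,
#'   `contact_table`, `exponent`, `expected_classes`.
#' @export
simulate_annotation_fixture <- function(seed = 0L, dir = tempdir(),
                                        exponent = -1, scale = 1e6) {
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(99901, 105001, 319901, 600001, 700001, 800001),
    end   = c(100100, 105500, 320100, 600500, 700400, 800500)))
  expected_classes <- data.frame(
    region_id = region_ids(peaks),
    class = c("promoter", "active_enhancer", "promoter", "poised_enhancer",
              "unannotated", "active_enhancer"),
    locality = c("not_applicable", "proximal", "not_applicable", "distal",
                 "not_applicable", "distal"),
    stringsAsFactors = FALSE)

  marks <- list(
    H3K4me3 = peaks[c(1L, 3L)],
    H3K4me1 = peaks[c(2L, 4L, 6L)],
    H3K27ac = peaks[c(2L, 6L)])

  gtf <- file.path(dir, "toy_genes.gtf")
  attr_a <- 'gene_id "GENEA"; transcript_id "GENEA.1";'
  attr_b <- 'gene_id "GENEB"; transcript_id "GENEB.1";'
  lines <- c(
    paste("chr1", "toy", "gene", 100001, 110000, ".", "+", ".",
          'gene_id "GENEA";', sep = "\t"),
    paste("chr1", "toy", "transcript", 100001, 110000, ".", "+", ".",
          attr_a, sep = "\t"),
    paste("chr1", "toy", "five_prime_utr", 100001, 100200, ".", "+", ".",
          attr_a, sep = "\t"),
    paste("chr1", "toy", "gene", 300001, 320000, ".", "-", ".",
          'gene_id "GENEB";', sep = "\t"),
    paste("chr1", "toy", "transcript", 300001, 320000, ".", "-", ".",
          attr_b, sep = "\t"),
    paste("chr1", "toy", "five_prime_utr", 319801, 320000, ".", "-", ".",
          attr_b, sep = "\t"))
  writeLines(lines, gtf)

  mark_files <- vapply(names(marks), function(nm) {
    f <- file.path(dir, paste0("mark_", nm, ".bed"))
    gr <- marks[[nm]]
    utils::write.table(
      data.frame(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr)),
      f, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    f
  }, character(1L))

  bin_size <- 5000L
  mid <- (GenomicRanges::start(peaks) - 1L + GenomicRanges::end(peaks)) %/% 2L
  bins <- mid %/% bin_size
  pairs <- expand.grid(i = seq_along(peaks), j = seq_along(peaks))
  pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
  d <- abs(mid[pairs$i] - mid[pairs$j])
  contact_table <- data.frame(
    chrom1 = "chr1", start1 = bins[pairs$i] * bin_size,
    end1 = (bins[pairs$i] + 1L) * bin_size,
    chrom2 = "chr1", start2 = bins[pairs$j] * bin_size,
    end2 = (bins[pairs$j] + 1L) * bin_size,
    score = scale * d^exponent)
  contacts_file <- file.path(dir, "toy_contacts.tsv")
  utils::write.table(contact_table, contacts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(gtf = gtf, marks = mark_files, contacts = contacts_file,
       peaks = peaks, mark_ranges = marks, contact_table = contact_table,
       exponent = exponent, expected_classes = expected_classes)
}
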