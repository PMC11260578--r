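# Functional annotation of accessible regions: histone-mark classes,
# promoter/enhancer locality, outlier-pair proximity enrichment, Hi-C
# contact scores, distance-controlled power regression, ABC scores.

#' Read gene models from a GTF file
#'
#' Parses a GENCODE-dialect GTF (1-based inclusive, converted internally)
#' and extracts gene bodies, strand-aware transcription start sites, and
#' 5' UTRs. Features typed `five_prime_utr` are used directly; plain `UTR`
#' features are treated as 5' when they touch the 5' end of their
#' transcript.
#'
#' @param gtf_file Path to a GTF file.
#' @return List of `GRanges`: `genes` (with `gene_id`), `tss` (width-1, with
#'   `gene_id`), `utr5` (with `gene_id`).
#' @export
read_gene_models <- function(gtf_file) {
  gtf <- rtracklayer::import(gtf_file, format = "gtf")
  genes <- gtf[gtf$type == "gene"]
  if (!length(genes)) {                      # derive from transcripts
    tx <- gtf[gtf$type == "transcript"]
    genes <- unlist(range(GenomicRanges::split(tx, tx$gene_id)))
    genes$gene_id <- names(genes)
  }
  tx <- gtf[gtf$type == "transcript"]
  if (!length(tx)) tx <- genes
  tss <- GenomicRanges::resize(tx, width = 1L, fix = "start")
  utr5 <- gtf[gtf$type == "five_prime_utr"]
  plain <- gtf[gtf$type == "UTR"]
  if (length(plain) && length(tx)) {
    tx_by_id <- stats::setNames(seq_along(tx), tx$transcript_id)
    m <- tx_by_id[as.character(plain$transcript_id)]
    ok <- !is.na(m)
    plain <- plain[ok]; m <- m[ok]
    fwd <- as.character(GenomicRanges::strand(plain)) != "-"
    is5 <- ifelse(fwd,
                  GenomicRanges::start(plain) == GenomicRanges::start(tx)[m],
                  GenomicRanges::end(plain) == GenomicRanges::end(tx)[m])
    utr5 <- c(utr5, plain[is5])
  }
  list(genes = genes, tss = tss, utr5 = utr5)
}

#' Classify accessible regions from histone marks and gene models
#'
#' Decision rules, in order of precedence: a region is a *promoter* if it
#' overlaps H3K4me3 and lies within `promoter_window` bp of a transcription
#' start site or overlaps a 5' UTR; otherwise an *active enhancer* if it
#' overlaps both H3K4me1 and H3K27ac; otherwise a *poised enhancer* if it
#' overlaps H3K4me1 alone; otherwise *unannotated*. Enhancers are *proximal*
#' when inside a gene body or at most `upstream` bp upstream / `downstream`
#' bp downstream of a gene (strand-aware), else *distal*. Any >= 1 bp
#' intersection counts as overlap.
#'
#' @param peaks `GRanges` (or BED-style data.frame) of accessible regions.
#' @param marks Named list of `GRanges` interval sets; recognised names
#'   `H3K4me3`, `H3K27ac`, `H3K4me1`. Missing marks make the dependent
#'   classes unreachable (warned).
#' @param genes Gene models from [read_gene_models()], or a list with
#'   elements `genes`, `tss`, `utr5`.
#' @param promoter_window TSS vicinity for promoters in bp (default 1000).
#' @param upstream,downstream Proximal-enhancer windows in bp (defaults
#'   10000 and 2000).
#' @return data.frame with columns `region_id`, `class`, `locality`, `genes`
#'   (comma-separated linked gene ids, `""` if none).
#' @export
classify_regions <- function(peaks, marks, genes, promoter_window = 1000,
                             upstream = 10000, downstream = 2000) {
  peaks <- as_granges(peaks)
  need <- c("H3K4me3", "H3K27ac", "H3K4me1")
  missing_marks <- setdiff(need, names(marks))
  if (length(missing_marks))
    warning("missing mark track(s): ", paste(missing_marks, collapse = ", "),
            "; dependent classes are unreachable")
  hit <- function(nm) {
    if (!nm %in% names(marks)) return(logical(length(peaks)))
    IRanges::overlapsAny(peaks, as_granges(marks[[nm]]),
                               ignore.strand = TRUE)
  }
  k4me3 <- hit("H3K4me3"); k27ac <- hit("H3K27ac"); k4me1 <- hit("H3K4me1")

  near_tss <- IRanges::overlapsAny(
    peaks, GenomicRanges::resize(genes$tss, width = 2 * promoter_window + 1L,
                                 fix = "center"), ignore.strand = TRUE)
  in_utr5 <- if (length(genes$utr5))
    IRanges::overlapsAny(peaks, genes$utr5, ignore.strand = TRUE)
  else logical(length(peaks))

  cls <- rep("unannotated", length(peaks))
  cls[k4me1] <- "poised_enhancer"
  cls[k4me1 & k27ac] <- "active_enhancer"
  cls[k4me3 & (near_tss | in_utr5)] <- "promoter"

  # strand-aware gene extension for proximal calls
  g <- genes$genes
  fwd <- as.character(GenomicRanges::strand(g)) != "-"
  ext_start <- GenomicRanges::start(g) - ifelse(fwd, upstream, downstream)
  ext_end <- GenomicRanges::end(g) + ifelse(fwd, downstream, upstream)
  gext <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                 IRanges::IRanges(pmax(ext_start, 1L), ext_end),
                                 gene_id = g$gene_id)
  near_gene <- IRanges::overlapsAny(peaks, gext, ignore.strand = TRUE)
  locality <- rep("not_applicable", length(peaks))
  enh <- cls %in% c("active_enhancer", "poised_enhancer")
  locality[enh] <- ifelse(near_gene[enh], "proximal", "distal")

  # gene linking: promoters via TSS window / 5'UTR, proximal enhancers via
  # the extended gene body
  linked <- character(length(peaks))
  tssw <- GenomicRanges::resize(genes$tss, width = 2 * promoter_window + 1L,
                                fix = "center")
  prom_hits <- GenomicRanges::findOverlaps(peaks, tssw, ignore.strand = TRUE)
  prom_genes <- split(genes$tss$gene_id[S4Vectors::subjectHits(prom_hits)],
                      S4Vectors::queryHits(prom_hits))
  if (length(genes$utr5)) {
    u_hits <- GenomicRanges::findOverlaps(peaks, genes$utr5, ignore.strand = TRUE)
    u_genes <- split(genes$utr5$gene_id[S4Vectors::subjectHits(u_hits)],
                     S4Vectors::queryHits(u_hits))
    for (i in names(u_genes))
      prom_genes[[i]] <- union(prom_genes[[i]], u_genes[[i]])
  }
  e_hits <- GenomicRanges::findOverlaps(peaks, gext, ignore.strand = TRUE)
  e_genes <- split(gext$gene_id[S4Vectors::subjectHits(e_hits)],
                   S4Vectors::queryHits(e_hits))
  for (i in seq_along(peaks)) {
    key <- as.character(i)
    ids <- if (cls[i] == "promoter") prom_genes[[key]]
    else if (locality[i] == "proximal") e_genes[[key]]
    linked[i] <- paste(unique(ids), collapse = ",")
  }
  data.frame(region_id = region_ids(peaks), class = cls, locality = locality,
             genes = linked, stringsAsFactors = FALSE)
}

#' Enrichment of outlier pairs in the proximity
#'
#' For each distance cutoff, enumerates every ordered pair of distinct
#' regions whose midpoints lie within that distance (irrespective of
#' status), cross-tabulates the two outlier statuses into a 2x2 table, and
#' reports the two-sided Fisher exact p-value together with the sample odds
#' ratio (`ad/bc`; Haldane-Anscombe 0.5 added to every cell when any cell is
#' empty, flagged in `corrected`). Also reports the fraction of outlier
#' regions having at least one outlier partner within the distance.
#'
#' @param regions `GRanges` of regions.
#' @param is_outlier Logical vector, one status per region (e.g. outlier in
#'   a given sample, or in any sample).
#' @param distances Distance cutoffs in bp (defaults 10 kb, 100 kb, 500 kb,
#'   1 Mb).
#' @return data.frame: `distance`, `odds_ratio`, `pvalue`,
#'   `fraction_second_outlier`, `n_pairs`, `corrected`.
#' @export
outlier_pair_enrichment <- function(regions, is_outlier,
                                    distances = c(1e4, 1e5, 5e5, 1e6)) {
  regions <- as_granges(regions)
  stopifnot(length(is_outlier) == length(regions))
  mid <- GenomicRanges::resize(regions, width = 1L, fix = "center")
  rows <- lapply(distances, function(d) {
    # width-1 midpoints at |p1 - p2| <= d have an interval gap of d - 1
    hits <- GenomicRanges::findOverlaps(mid, maxgap = max(d - 1, 0),
                                        ignore.strand = TRUE,
                                        drop.self = TRUE, drop.redundant = FALSE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    a <- sum(is_outlier[qi] & is_outlier[si])
    b <- sum(is_outlier[qi] & !is_outlier[si])
    cc <- sum(!is_outlier[qi] & is_outlier[si])
    dd <- sum(!is_outlier[qi] & !is_outlier[si])
    tab <- matrix(c(a, cc, b, dd), 2L)
    corrected <- any(tab == 0)
    or <- if (corrected) ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * dd) / (b * cc)
    p <- if (sum(tab) > 0) stats::fisher.test(tab)$p.value else NA_real_
    frac <- if (any(is_outlier)) {
      with_partner <- unique(qi[is_outlier[qi] & is_outlier[si]])
      length(with_partner) / sum(is_outlier)
    } else NA_real_
    data.frame(distance = d, odds_ratio = or, pvalue = p,
               fraction_second_outlier = frac, n_pairs = length(qi),
               corrected = corrected)
  })
  do.call(rbind, rows)
}

#' Build a binned Hi-C contact map
#'
#' Takes a BEDPE-like pairs table (`chrom1, start1, end1, chrom2, start2,
#' end2, score`) and bins each anchor by its midpoint at `bin_size`
#' resolution, storing the map symmetrically (duplicate bin pairs keep the
#' maximum score).
#'
#' @param pairs data.frame with the seven BEDPE-like columns (BED 0-based
#'   starts), or a path to such a TSV.
#' @param bin_size Bin width in bp (default 5000).
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(pairs, bin_size = 5000) {
  if (is.character(pairs))
    pairs <- utils::read.table(pairs, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "score")
  stopifnot(all(need %in% names(pairs)), all(pairs$score >= 0))
  b1 <- (pairs$start1 + pairs$end1) %/% 2L %/% bin_size
  b2 <- (pairs$start2 + pairs$end2) %/% 2L %/% bin_size
  dt <- data.table::data.table(
    chrom1 = c(pairs$chrom1, pairs$chrom2), bin1 = c(b1, b2),
    chrom2 = c(pairs$chrom2, pairs$chrom1), bin2 = c(b2, b1),
    score = c(pairs$score, pairs$score))
  dt <- dt[, list(score = max(score)), by = c("chrom1", "bin1", "chrom2", "bin2")]
  data.table::setkeyv(dt, c("chrom1", "bin1", "chrom2", "bin2"))
  structure(list(contacts = dt, bin_size = bin_size), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d bin pairs at %d bp resolution\n",
              nrow(x$contacts), x$bin_size))
  invisible(x)
}

region_bin <- function(region, bin_size) {
  region <- as_granges(region)
  mid0 <- (GenomicRanges::start(region) - 1L + GenomicRanges::end(region)) %/% 2L
  list(chrom = as.character(GenomicRanges::seqnames(region)),
       bin = mid0 %/% bin_size)
}

#' Hi-C contact score between two regions
#'
#' Maps each region to the bin of its midpoint and returns the maximum
#' contact score over the 3x3 neighborhood of (source bin +/- 1) x
#' (target bin +/- 1); bins below zero are truncated at the chromosome
#' boundary. Symmetric in its arguments. Returns 0 when no contact is
#' recorded in the neighborhood.
#'
#' @param source,target Single-region `GRanges` (or 1-row BED data.frames).
#' @param contacts A [contact_map()].
#' @return Non-negative scalar contact score.
#' @export
hic_contact <- function(source, target, contacts) {
  stopifnot(inherits(contacts, "contact_map"))
  s <- region_bin(source, contacts$bin_size)
  t <- region_bin(target, contacts$bin_size)
  sb <- unique(pmax(s$bin + (-1L:1L), 0L))
  tb <- unique(pmax(t$bin + (-1L:1L), 0L))
  grid <- data.table::CJ(chrom1 = s$chrom, bin1 = sb, chrom2 = t$chrom, bin2 = tb)
  hit <- contacts$contacts[grid, nomatch = NULL]
  if (nrow(hit) == 0L) 0 else max(hit$score)
}

#' Distance-controlled power regression of contact scores
#'
#' Fits `ln(contact + offset) = b0 + b1 ln(distance) + b2 outlier_pair` by
#' ordinary least squares: a power-law distance decay with a multiplicative
#' term testing whether outlier pairs have elevated contact. Coefficient
#' p-values are two-sided t-tests.
#'
#' @param pairs data.frame with columns `contact` (>= 0), `distance` (> 0),
#'   and optionally `outlier_pair` (logical).
#' @param offset Added inside the log of the response (default 1).
#' @return List with `coefficients` (estimate, std_error, t, pvalue per
#'   term) and `fit` (the `lm` object).
#' @export
distance_power_regression <- function(pairs, offset = 1) {
  stopifnot(all(c("contact", "distance") %in% names(pairs)),
            all(pairs$distance > 0), all(pairs$contact >= 0))
  df <- data.frame(y = log(pairs$contact + offset),
                   log_distance = log(pairs$distance))
  form <- y ~ log_distance
  if ("outlier_pair" %in% names(pairs)) {
    df$outlier_pair <- as.numeric(pairs$outlier_pair)
    form <- y ~ log_distance + outlier_pair
  }
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm), estimate = sm[, 1L],
                                 std_error = sm[, 2L], t = sm[, 3L],
                                 pvalue = sm[, 4L], row.names = NULL),
       fit = fit)
}

#' Approximate contact scores from a power-law distance decay
#'
#' `score = exp(b0) * distance^b1`, with zero distances clamped to one bin
#' size. Use coefficients from [distance_power_regression()] fitted on
#' available Hi-C data (intercept and `log_distance` slope).
#'
#' @param distance Numeric vector of genomic distances in bp.
#' @param intercept,slope Power-law coefficients `b0`, `b1`.
#' @param bin_size Clamp for zero distances (default 5000).
#' @return Predicted contact scores.
#' @export
approximate_contacts <- function(distance, intercept, slope, bin_size = 5000) {
  exp(intercept) * pmax(distance, bin_size)^slope
}

#' Activity-by-contact (ABC) scores for one source region
#'
#' For a source region `s` (typically a promoter) and the candidate target
#' regions within `vicinity` bp, `ABC(s -> t) = h(s, t) * k_t / sum_i h(s, i)
#' * k_i`, where `h` is the Hi-C contact score ([hic_contact()]) and `k_t`
#' the total accessibility of the target (counts summed over samples).
#' Scores sum to 1 over the vicinity whenever the denominator is positive;
#' a zero denominator yields `NA` scores.
#'
#' @param source Single-region `GRanges`.
#' @param targets `GRanges` of candidate target regions.
#' @param contacts A [contact_map()].
#' @param accessibility Numeric vector `k_t`, one per target.
#' @param vicinity Radius in bp around the source midpoint (default 1e6).
#' @return data.frame: `target_id`, `distance`, `h`, `abc` (only targets
#'   within the vicinity).
#' @export
abc_scores <- function(source, targets, contacts, accessibility,
                       vicinity = 1e6) {
  source <- as_granges(source)
  targets <- as_granges(targets)
  stopifnot(length(source) == 1L, length(accessibility) == length(targets))
  smid <- GenomicRanges::resize(source, width = 1L, fix = "center")
  tmid <- GenomicRanges::resize(targets, width = 1L, fix = "center")
  same <- as.character(GenomicRanges::seqnames(tmid)) ==
    as.character(GenomicRanges::seqnames(smid))
  dist <- abs(GenomicRanges::start(tmid) - GenomicRanges::start(smid))
  keep <- which(same & dist <= vicinity)
  if (!length(keep))
    return(data.frame(target_id = character(), distance = numeric(),
                      h = numeric(), abc = numeric()))
  h <- vapply(keep, function(i) hic_contact(source, targets[i], contacts),
              numeric(1L))
  w <- h * accessibility[keep]
  denom <- sum(w)
  abc <- if (denom > 0) w / denom else {
    warning("zero ABC denominator for source ", region_ids(source))
    rep(NA_real_, length(w))
  }
  data.frame(target_id = region_ids(targets[keep]), distance = dist[keep],
             h = h, abc = abc)
}
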