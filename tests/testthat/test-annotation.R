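fx <- simulate_annotation_fixture(seed = 1, dir = withr::local_tempdir(
  .local_envir = teardown_env()))
genes <- read_gene_models(fx$gtf)

test_that("the toy fixture realises every region class and the classifier finds them", {
  ann <- classify_regions(fx$peaks, fx$mark_ranges, genes)
  expect_equal(ann$class, fx$expected_classes$class)
  expect_equal(ann$locality, fx$expected_classes$locality)
  # one class of each kind is present
  expect_setequal(unique(ann$class),
                  c("promoter", "active_enhancer", "poised_enhancer",
                    "unannotated"))
  expect_true(all(c("proximal", "distal") %in% ann$locality))
  # promoters and proximal enhancers link their genes
  expect_equal(ann$genes[1], "GENEA")
  expect_equal(ann$genes[3], "GENEB")
  expect_equal(ann$genes[2], "GENEA")
})

test_that("promoter takes precedence over enhancer marks", {
  marks <- fx$mark_ranges
  # give the GENEA promoter peak all three marks
  marks$H3K4me1 <- c(marks$H3K4me1, fx$peaks[1])
  marks$H3K27ac <- c(marks$H3K27ac, fx$peaks[1])
  ann <- classify_regions(fx$peaks, marks, genes)
  expect_equal(ann$class[1], "promoter")
})

test_that("a missing mark track narrows the reachable classes with a warning", {
  expect_warning(
    ann <- classify_regions(fx$peaks, fx$mark_ranges[c("H3K4me3", "H3K4me1")],
                            genes),
    "H3K27ac")
  expect_false("active_enhancer" %in% ann$class)
  expect_equal(sum(ann$class == "poised_enhancer"), 3L)
})

test_that("strand-aware proximal windows behave asymmetrically", {
  # 5 kb upstream of GENEA (TSS 100001, + strand): proximal (<= 10 kb up)
  up5 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(95001, 95200))
  # 5 kb downstream of GENEA end (110000): distal (> 2 kb down)
  down5 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(115001, 115200))
  marks <- list(H3K4me1 = c(up5, down5))
  expect_warning(ann <- classify_regions(c(up5, down5), marks, genes))
  expect_equal(ann$locality, c("proximal", "distal"))
})

test_that("outlier pair enrichment matches the exact 2x2 oracle", {
  # [[10, 2], [2, 10]]: sample OR 25, p from exact hypergeometric enumeration
  tab <- matrix(c(10, 2, 2, 10), 2)
  enum_p <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
    support <- max(0, kk - n):min(kk, m)
    probs <- dhyper(support, m, n, kk)
    sum(probs[probs <= dhyper(tab[1, 1], m, n, kk) * (1 + 1e-7)])
  }
  expect_equal(fisher.test(tab)$p.value, enum_p(tab), tolerance = 1e-9)

  # construction: outlier pairs planted within 10 kb only
  starts <- c(seq(1e4, 5e4, by = 2e3), seq(5e6, 5.04e6, by = 2e3))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 500))
  status <- rep(FALSE, length(gr))
  status[1:6] <- TRUE              # clustered outliers
  enr <- outlier_pair_enrichment(gr, status, distances = c(1e4, 1e6))
  expect_gt(enr$odds_ratio[1], enr$odds_ratio[2])
  expect_true(all(enr$n_pairs > 0))

  # null case: random statuses -> OR near 1, p clearly non-significant
  set.seed(81)
  pos <- sort(sample.int(5e6, 300))
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 100))
  st2 <- runif(300) < 0.3
  enr2 <- outlier_pair_enrichment(gr2, st2, distances = 1e6)
  expect_gt(enr2$pvalue[1], 0.01)
  expect_lt(abs(log(enr2$odds_ratio[1])), log(2.5))
})

test_that("hic_contact takes the 3x3 neighborhood maximum", {
  cm <- contact_map(data.frame(
    chrom1 = "chr1", start1 = c(10000, 15000), end1 = c(15000, 20000),
    chrom2 = "chr1", start2 = c(50000, 45000), end2 = c(55000, 50000),
    score = c(7, 9)))
  src <- GenomicRanges::GRanges("chr1", IRanges::IRanges(12000, 12400))
  tgt <- GenomicRanges::GRanges("chr1", IRanges::IRanges(52000, 52400))
  # direct bin pair scores 7, neighbor (bin+1, bin-1) scores 9 -> 9
  expect_equal(hic_contact(src, tgt, cm), 9)
  # symmetry
  expect_equal(hic_contact(tgt, src, cm), 9)
  # far away -> 0
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900000, 900400))
  expect_equal(hic_contact(src, far, cm), 0)

  # randomized maps vs brute force over the 9 bin pairs
  set.seed(82)
  for (rep in 1:15) {
    bins <- sample.int(60, 40, replace = TRUE)
    df <- data.frame(chrom1 = "chr1", start1 = bins * 5000,
                     end1 = (bins + 1) * 5000,
                     chrom2 = "chr1", start2 = rev(bins) * 5000,
                     end2 = (rev(bins) + 1) * 5000,
                     score = runif(40, 0, 100))
    cmr <- contact_map(df)
    s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(sample.int(3e5, 1),
                                                         width = 300))
    t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(sample.int(3e5, 1),
                                                         width = 300))
    sb <- (GenomicRanges::start(s) - 1 + GenomicRanges::end(s)) %/% 2 %/% 5000
    tb <- (GenomicRanges::start(t) - 1 + GenomicRanges::end(t)) %/% 2 %/% 5000
    best <- 0
    for (a in (sb - 1):(sb + 1)) for (b in (tb - 1):(tb + 1)) {
      hit <- c(df$score[(bins == a & rev(bins) == b) |
                          (bins == b & rev(bins) == a)])
      if (length(hit)) best <- max(best, hit)
    }
    expect_equal(hic_contact(s, t, cmr), best)
  }
})

test_that("distance power regression recovers a planted decay and flags boosts", {
  set.seed(83)
  d <- exp(runif(300, log(5e3), log(2e6)))
  contact <- 3e5 * d^-1.1
  fit <- distance_power_regression(data.frame(contact = contact, distance = d),
                                   offset = 0)
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "log_distance"], -1.1, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "(Intercept)"], log(3e5),
               tolerance = 1e-6)

  outlier_pair <- runif(300) < 0.3
  boosted <- contact * ifelse(outlier_pair, 3, 1)
  fit2 <- distance_power_regression(
    data.frame(contact = boosted, distance = d, outlier_pair = outlier_pair),
    offset = 0)
  co2 <- fit2$coefficients
  expect_gt(co2$estimate[co2$term == "outlier_pair"], 0)
  expect_lt(co2$pvalue[co2$term == "outlier_pair"], 1e-6)

  # closed-form OLS oracle on a 10-row table
  small <- data.frame(contact = exp(rnorm(10, 3)), distance = exp(rnorm(10, 8)))
  fs <- distance_power_regression(small)
  X <- cbind(1, log(small$distance))
  beta <- solve(crossprod(X), crossprod(X, log(small$contact + 1)))
  expect_equal(fs$coefficients$estimate, as.numeric(beta), tolerance = 1e-9)
})

test_that("the fixture's contact table regression recovers the planted exponent", {
  pairs <- data.frame(
    contact = fx$contact_table$score,
    distance = abs((fx$contact_table$start1 + fx$contact_table$end1) / 2 -
                     (fx$contact_table$start2 + fx$contact_table$end2) / 2))
  fit <- distance_power_regression(pairs, offset = 0)
  est <- fit$coefficients$estimate[fit$coefficients$term == "log_distance"]
  # bin-midpoint distances only approximate peak-midpoint distances
  expect_equal(est, fx$exponent, tolerance = 0.05)
})

test_that("ABC scores normalize over the vicinity", {
  cm <- contact_map(fx$contacts)
  src <- fx$peaks[1]                        # the GENEA promoter
  targets <- fx$peaks[-1]
  k_t <- c(500, 300, 800, 100, 200)
  abc <- abc_scores(src, targets, cm, k_t, vicinity = 1e6)
  expect_equal(sum(abc$abc), 1, tolerance = 1e-12)
  expect_true(all(abc$abc >= 0 & abc$abc <= 1))

  # single target -> 1; equal h*k -> 0.5 each
  one <- abc_scores(src, targets[1], cm, 500)
  expect_equal(one$abc, 1)
  two <- abc_scores(src, fx$peaks[c(2, 2)], cm, c(400, 400))
  expect_equal(two$abc, c(0.5, 0.5))

  # zero accessibility everywhere -> undefined with warning
  expect_warning(zz <- abc_scores(src, targets, cm, rep(0, 5)), "denominator")
  expect_true(all(is.na(zz$abc)))
})

test_that("approximate_contacts follows the fitted power law", {
  expect_equal(approximate_contacts(10, intercept = 0, slope = -1,
                                    bin_size = 1), 0.1)
  # zero distance clamps to one bin
  expect_equal(approximate_contacts(0, 0, -1), approximate_contacts(5000, 0, -1))
  d <- c(1e4, 1e5, 1e6)
  sc <- approximate_contacts(d, intercept = 12, slope = -1.08)
  expect_true(all(diff(sc) < 0))
})
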