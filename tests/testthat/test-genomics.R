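test_that("peak-per-gene counting uses half-open 1 bp overlap semantics", {
  genes <- data.frame(chrom = "chr1", start = c(299L, 300L, 1000L),
                      end = c(500L, 500L, 2000L))
  peaks <- data.frame(chrom = "chr1", start = c(100L, 1200L, 1400L),
                      end = c(300L, 1400L, 1600L))
  # peak [100,300) overlaps gene [299,500) by 1 bp, abuts gene [300,500)
  expect_equal(count_peaks_per_gene(peaks, genes), c(1L, 0L, 2L))
  # agreement with a per-base-pair brute-force oracle on random toy genomes
  set.seed(51)
  for (i in 1:10) {
    ps <- sort(sample(0:9000, 20)); pe <- ps + sample(50:400, 20, replace = TRUE)
    gs <- sort(sample(0:9000, 6)); ge <- gs + sample(200:1500, 6, replace = TRUE)
    got <- count_peaks_per_gene(
      data.frame(chrom = "t", start = ps, end = pe),
      data.frame(chrom = "t", start = gs, end = ge))
    want <- vapply(seq_along(gs), function(j)
      oracle_peak_count(ps, pe, gs[j], ge[j]), integer(1))
    expect_equal(got, want)
  }
  expect_error(granges_from_bed(
    data.frame(chrom = "t", start = 10L, end = 10L)), "malformed")
})

test_that("pairwise correlation handles identity, inversion and the null", {
  x <- c(1.2, 5, 2.3, 8, 4.4, 0.5)
  expect_equal(pairwise_correlation(x, x, method = "pearson")$r, 1)
  expect_equal(pairwise_correlation(x, -x, method = "pearson")$r, -1)
  expect_error(pairwise_correlation(x, rep(2, 6)), "zero variance")
  expect_error(pairwise_correlation(x[1:3], x[1:3]), "n >= 4")
  ok <- vapply(1:60, function(s) {
    set.seed(5000 + s)
    abs(pairwise_correlation(rnorm(1000), rnorm(1000),
                             method = "pearson")$r) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(30:300, 1)
    z <- rnorm(n)
    x <- 0.8 * z + rnorm(n)
    y <- -0.5 * z + rnorm(n)
    pc <- partial_correlation(x, y, z)
    expect_equal(pc$r, oracle_partial_residual(x, y, z), tolerance = 1e-10)
  }
  # no confounding: r_xy.z equals r_xy
  set.seed(53)
  x <- rnorm(200); y <- x + rnorm(200); z <- rnorm(200)
  pc <- partial_correlation(x, y, z)
  # construction x = z + e1, y = z + e2: partial ~ 0 while pairwise >> 0
  z2 <- rnorm(2000); x2 <- z2 + rnorm(2000); y2 <- z2 + rnorm(2000)
  pw2 <- pairwise_correlation(x2, y2, method = "pearson")
  pc2 <- partial_correlation(x2, y2, z2)
  expect_gt(pw2$r, 0.3)
  expect_lt(abs(pc2$r), 0.1)
  expect_error(partial_correlation(x2, y2, x2), "degenerate")
})

test_that("confounder-only genes: pairwise r positive, partial CI covers 0", {
  res <- vapply(1:100, function(s) {
    g <- sim_gene_peak_table(genomics_sim_config(
      n_genes = 400, expression_effect = 0.4, direct_association = 0,
      seed = s))
    pw <- pairwise_correlation(g$genes$ino80_abundance,
                               g$genes$drip_abundance, method = "pearson")
    pc <- partial_correlation(g$genes$ino80_abundance,
                              g$genes$drip_abundance, g$genes$expression)
    c(pw = pw$r, covered = pc$ci_lower <= 0 && 0 <= pc$ci_upper)
  }, numeric(2))
  expect_true(all(res["pw", ] > 0))
  expect_gte(mean(res["covered", ]), 0.85)
  # with a direct association both correlations stay positive
  g1 <- sim_gene_peak_table(genomics_sim_config(
    n_genes = 800, expression_effect = 0.4, direct_association = 1.5,
    seed = 3))
  pc1 <- partial_correlation(g1$genes$ino80_abundance,
                             g1$genes$drip_abundance, g1$genes$expression)
  expect_gt(pc1$r, 0.2)
  expect_lt(pc1$p_value, 1e-6)
})

test_that("bin classification partitions the genome by peak presence", {
  bins <- make_genome_bins(c(toy = 2000L), bin_width = 200L)
  expect_equal(length(bins), 10L)
  ino <- data.frame(chrom = "toy", start = c(0L, 800L), end = c(200L, 1000L))
  drip <- data.frame(chrom = "toy", start = c(150L, 1200L),
                     end = c(350L, 1250L))
  cls <- classify_peak_overlap(ino, drip, bins)
  expect_identical(as.character(cls[1]), "INO80+DRIP")
  expect_identical(as.character(cls[2]), "DRIP")     # [200,400) touches [150,350)
  expect_identical(as.character(cls[5]), "INO80")
  expect_identical(as.character(cls[7]), "DRIP")
  expect_identical(as.character(cls[10]), "NoDRIP+NoINO80")
  expect_equal(sum(table(cls)), length(bins))
})

test_that("state enrichment obeys arithmetic cases and the conservation identity", {
  # class entirely inside a state covering 10% of the genome -> fold 10
  seg <- data.frame(chrom = "toy", start = c(0L, 100L), end = c(100L, 1000L),
                    state = c("state_1", "state_2"))
  cls <- list(hits = data.frame(chrom = "toy", start = 0L, end = 100L))
  em <- state_enrichment(seg, cls)
  expect_equal(em$fold_hits[em$state == "state_1"], 10)
  expect_equal(em$fold_hits[em$state == "state_2"], 0)
  expect_equal(sum(em$genome_fraction), 1)
  # proportionally distributed class -> all folds 1
  cls2 <- list(unif = data.frame(chrom = "toy", start = c(0L, 100L),
                                 end = c(50L, 550L)))
  em2 <- state_enrichment(seg, cls2)
  expect_equal(em2$fold_unif, c(1, 1))
  # conservation: genome-fraction-weighted mean fold = 1 on random segmentations
  for (s in 1:20) {
    g <- sim_gene_peak_table(genomics_sim_config(n_genes = 60, seed = s))
    bins <- make_genome_bins(c(chrS = g$genome_length))
    cl <- classify_peak_overlap(g$peaks_ino80, g$peaks_drip, bins)
    regions <- lapply(split(bins, cl), GenomicRanges::reduce)
    regions <- regions[vapply(regions, length, 1L) > 0]
    em3 <- state_enrichment(g$states, regions)
    for (col in grep("^fold_", names(em3), value = TRUE))
      expect_equal(sum(em3$genome_fraction * em3[[col]]), 1,
                   tolerance = 1e-12)
  }
  expect_warning(state_enrichment(seg, list(
    off = data.frame(chrom = "elsewhere", start = 0L, end = 50L))),
    "no bp inside")
})

test_that("DRIP-qPCR enrichment is input-corrected and control-normalized", {
  expect_equal(drip_qpcr_enrichment(3, 2, 3, 2)$fold_enrichment, 1)
  expect_equal(drip_qpcr_enrichment(6, 2, 3, 2)$fold_enrichment, 2)
  mock <- drip_qpcr_enrichment(0.01, 2, 3, 2)
  expect_lt(mock$fold_enrichment, 0.05)
  expect_true(mock$background)
  expect_error(drip_qpcr_enrichment(1, 0, 1, 1), "positive")
})
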