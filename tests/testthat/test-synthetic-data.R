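test_that("fibre generator honours degenerate regimes and reproducibility", {
  # no stalls, no speed noise -> all ratios exactly 1
  f <- sim_fibre_population(fibre_sim_config(
    n_tracks = 40, speed_sd = 0, stall_prob = 0, seed = 2))
  expect_equal(asymmetry_ratio(f$pairs$left_um, f$pairs$right_um),
               rep(1, 40))
  # full stalling at severity 0.5 -> all ratios exactly 2
  f2 <- sim_fibre_population(fibre_sim_config(
    n_tracks = 40, speed_sd = 0, stall_prob = 1, stall_severity = 0.5,
    seed = 2))
  expect_equal(asymmetry_ratio(f2$pairs$left_um, f2$pairs$right_um),
               rep(2, 40))
  expect_true(all(f2$pairs$stalled))
  # empty population
  expect_identical(nrow(sim_fibre_population(
    fibre_sim_config(n_tracks = 0))$pairs), 0L)
  # identical config + seed -> bitwise identical tables
  expect_identical(sim_fibre_population(fibre_sim_config(seed = 9)),
                   sim_fibre_population(fibre_sim_config(seed = 9)))
  expect_error(fibre_sim_config(stall_prob = 1.2))
})

test_that("volume generator produces the promised overlap structure", {
  # coloc_fraction 1, no noise: every B object shares a voxel with A
  v1 <- sim_two_channel_volume(volume_sim_config(
    shape = c(48L, 48L, 48L), n_objects_a = 15, n_objects_b = 15,
    coloc_fraction = 1, noise_sd = 0, seed = 3))
  oa <- segment_objects(v1$channel_a, 1, channel = "A")
  ob <- segment_objects(v1$channel_b, 1, channel = "B")
  expect_equal(coloc_by_voxel_overlap(oa, ob)$summary$pct_coloc, 100)
  # coloc_fraction 0 with enforced separation: zero shared voxels
  v0 <- sim_two_channel_volume(volume_sim_config(
    shape = c(48L, 48L, 48L), n_objects_a = 15, n_objects_b = 15,
    coloc_fraction = 0, noise_sd = 0, seed = 3))
  oa0 <- segment_objects(v0$channel_a, 1, channel = "A")
  ob0 <- segment_objects(v0$channel_b, 1, channel = "B")
  expect_equal(coloc_by_voxel_overlap(oa0, ob0)$summary$n_coloc, 0L)
  # reproducibility
  expect_identical(v1$truth, sim_two_channel_volume(volume_sim_config(
    shape = c(48L, 48L, 48L), n_objects_a = 15, n_objects_b = 15,
    coloc_fraction = 1, noise_sd = 0, seed = 3))$truth)
})

test_that("truth coloc counts are binomial across seeds", {
  p <- 0.4; n_b <- 30
  counts <- vapply(1:60, function(s) {
    v <- sim_two_channel_volume(volume_sim_config(
      shape = c(48L, 48L, 48L), n_objects_a = 20, n_objects_b = n_b,
      coloc_fraction = p, noise_sd = 0, seed = s))
    sum(v$truth$coloc[v$truth$channel == "B"])
  }, numeric(1))
  # mean within 4 SE of n*p and variance on the binomial scale
  se <- sqrt(n_b * p * (1 - p) / 60)
  expect_lt(abs(mean(counts) - n_b * p), 4 * se)
  expect_gt(var(counts), n_b * p * (1 - p) * 0.4)
  expect_lt(var(counts), n_b * p * (1 - p) * 2.5)
})

test_that("latent kinetics path is integer, non-negative and has the M/M/inf mean", {
  # no resolution -> non-decreasing; no formation -> non-increasing to 0
  up <- sim_locus_trace(kinetics_sim_config(
    resolution_rate = 0, reporter_noise_sd = 0, seed = 4))
  expect_true(all(diff(up$latent$n) >= 0))
  down <- sim_locus_trace(kinetics_sim_config(
    formation_rate = 0, n0 = 30L, seed = 4))
  expect_true(all(diff(down$latent$n) <= 0))
  expect_equal(down$latent$n[nrow(down$latent)], 0)
  # integer-valued, non-negative
  tr <- sim_locus_trace(kinetics_sim_config(seed = 5))
  expect_true(all(tr$latent$n >= 0))
  expect_true(all(tr$latent$n == round(tr$latent$n)))
  expect_true(all(tr$trace$reporter > 0))
  # long-run mean ~ lambda/mu (M/M/infinity stationary mean), MC error bound
  lam <- 0.5; mu <- 0.05
  means <- vapply(1:40, function(s) {
    x <- sim_locus_trace(kinetics_sim_config(
      formation_rate = lam, resolution_rate = mu, n0 = 10L,
      duration_min = 3000, seed = s))
    mean(x$latent$n[x$latent$t_min > 1000])
  }, numeric(1))
  expect_lt(abs(mean(means) - lam / mu), 4 * sd(means) / sqrt(length(means)))
  # reproducibility
  expect_identical(tr, sim_locus_trace(kinetics_sim_config(seed = 5)))
})

test_that("gene/peak generator encodes the confounding structure it claims", {
  g <- sim_gene_peak_table(genomics_sim_config(n_genes = 300, seed = 6))
  # BED peak counts reproduce the abundance columns
  expect_equal(count_peaks_per_gene(g$peaks_ino80, g$genes),
               g$genes$ino80_abundance)
  expect_equal(count_peaks_per_gene(g$peaks_drip, g$genes),
               g$genes$drip_abundance)
  # segmentation partitions the toy genome exactly
  expect_equal(g$states$start[1], 0)
  expect_equal(g$states$end[nrow(g$states)], g$genome_length)
  expect_equal(g$states$start[-1], g$states$end[-nrow(g$states)])
  expect_setequal(unique(g$states$state), paste0("state_", 1:8))
  # no confounder (expression_effect = 0): pairwise ~ partial
  g0 <- sim_gene_peak_table(genomics_sim_config(
    n_genes = 1000, expression_effect = 0, direct_association = 1.5,
    seed = 6))
  pw <- pairwise_correlation(g0$genes$ino80_abundance,
                             g0$genes$drip_abundance, method = "pearson")
  pc <- partial_correlation(g0$genes$ino80_abundance,
                            g0$genes$drip_abundance, g0$genes$expression)
  expect_lt(abs(pw$r - pc$r), 0.05)
  expect_gt(pc$r, 0.2)
  # reproducibility
  expect_identical(g, sim_gene_peak_table(genomics_sim_config(
    n_genes = 300, seed = 6)))
})

test_that("growth plate generator encodes multiplicative interaction", {
  # independence null, no noise: combined equals the product exactly
  p1 <- sim_growth_plate(0.5, 0.8, interaction = 1, n_wells = 4, seed = 8)
  m <- tapply(p1$growth, p1$condition, mean)
  expect_equal(unname(m[["combined"]]), 0.5 * 0.8)
  # interaction 4 with effects (0.2, 0.9): observed / predicted = 4
  p4 <- sim_growth_plate(0.2, 0.9, interaction = 4, n_wells = 4, seed = 8)
  m4 <- tapply(p4$growth, p4$condition, mean)
  v <- predicted_independent_growth(100 * m4[["a"]], 100 * m4[["b"]])
  expect_equal(rescue_fold(100 * m4[["combined"]], v), 4)
  # well-to-well SD of combined growth ~ noise_sd
  sds <- vapply(1:60, function(s)
    sd(subset(sim_growth_plate(0.6, 0.7, 1, n_wells = 24,
                               noise_sd = 0.05, seed = s),
              condition == "combined")$growth), numeric(1))
  expect_lt(abs(mean(sds) - 0.05), 0.01)
  expect_error(sim_growth_plate(0.5, 0.8, n_wells = 0))
  expect_error(sim_growth_plate(2, 0.8))
})
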