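test_that("bin grid tiles genomes exactly, truncating the last bin", {
  g <- build_bin_grid(data.frame(chrom = "chr1", length = 100000),
                      bin_size = 20000)
  expect_equal(nrow(g), 5)
  expect_equal(g$start, seq(0, 80000, by = 20000))
  expect_equal(max(g$end), 100000)

  g2 <- build_bin_grid(data.frame(chrom = "chr1", length = 95000),
                       bin_size = 20000)
  expect_equal(nrow(g2), 5)
  expect_equal(g2$end[5] - g2$start[5], 15000)

  expect_error(build_bin_grid(data.frame(chrom = character(0),
                                         length = numeric(0)), 20000),
               "empty genome")
  expect_error(build_bin_grid(data.frame(chrom = "c", length = 1e5), -1),
               "bin_size")
})

test_that("bin count matches brute-force enumeration on a many-chromosome genome", {
  set.seed(3)
  genome <- data.frame(chrom = paste0("chr", 1:22),
                       length = sample(5e6:2e7, 22))
  g <- build_bin_grid(genome, bin_size = 20000)
  # oracle: enumerate bin starts chromosome by chromosome
  oracle <- sum(vapply(genome$length,
                       function(L) length(seq(0, L - 1, by = 20000)), 0L))
  expect_equal(nrow(g), oracle)
  expect_equal(nrow(g), sum(ceiling(genome$length / 20000)))
  # half-open invariants
  expect_true(all(g$end > g$start))
  expect_true(all(g$gc > 0 & g$gc < 1))
  expect_true(all(g$mappability >= 0 & g$mappability <= 1))
})

test_that("copy-state phenotypes follow the profile definitions", {
  cfg <- small_config(nsmp_n_range = c(0L, 0L))
  grid <- build_bin_grid(cfg$genome, cfg$bin_size, seed = 2)
  # NSMP with alteration rate 0: all copy 2
  cs <- simulate_copy_states("NSMP", grid, cfg, seed = 5)
  expect_true(all(cs == 2L))
  expect_false(attr(cs, "hrd_like"))

  # CCNE1: at least one bin over the locus at copy >= 3
  loc <- cfg$ccne1_locus
  for (s in 1:10) {
    cs <- simulate_copy_states("CCNE1", grid, cfg, seed = s)
    ov <- bins_overlapping(grid, loc$chrom, loc$start, loc$end)
    expect_gte(max(cs[ov]), 3L)
  }
  # non-CCNE1 genomes never touch the locus (truth exclusivity)
  for (s in 1:10) {
    cs <- simulate_copy_states("nonBRCAmutHRD", grid, cfg, seed = s)
    ov <- bins_overlapping(grid, loc$chrom, loc$start, loc$end)
    expect_true(all(cs[ov] == 2L))
  }
  expect_error(sim_config(genome = small_genome(),
                          ccne1_locus = list(chrom = "chrX", start = 0,
                                             end = 1e5)),
               "locus")
})

test_that("HRD altered fraction matches the analytic mean over 500 draws", {
  cfg <- small_config()
  G <- sum(cfg$genome$length)
  hs <- cfg$hrd_signature
  exp_frac <- (sum(hs$rec_prob * (hs$regions$end - hs$regions$start)) +
                 mean(hs$n_scatter_range[1]:hs$n_scatter_range[2]) *
                 mean(hs$scatter_len_range)) / G
  fracs <- vapply(1:500, function(s) {
    segs <- simulate_cn_segments("nonBRCAmutHRD", cfg, seed = 1000 + s)
    sum(segs$end - segs$start) / G
  }, 0)
  expect_lt(abs(mean(fracs) - exp_frac) / exp_frac, 0.10)
})

test_that("read counts follow the negative-binomial mean model", {
  grid <- flat_grid(n_bins = 10000)
  grid$mappability <- runif(10000, 0.7, 1)
  cfg <- sim_config(genome = small_genome(), gc_bias_strength = 0,
                    dispersion = 0, mean_depth = 50)
  cs <- rep(2L, 10000)
  counts <- simulate_read_counts(cs, grid, cfg, seed = 4)
  # law of large numbers against the formula mean_depth * mappability
  expect_lt(abs(mean(counts) - mean(50 * grid$mappability)) /
              mean(50 * grid$mappability), 0.02)

  # copy 4 vs copy 2 doubles the expectation
  cs4 <- rep(c(2L, 4L), each = 5000)
  c4 <- simulate_read_counts(cs4, grid, cfg, seed = 9)
  r <- mean(c4[5001:10000] / grid$mappability[5001:10000]) /
    mean(c4[1:5000] / grid$mappability[1:5000])
  expect_lt(abs(r - 2), 0.05)

  # determinism and error handling
  expect_identical(simulate_read_counts(cs, grid, cfg, seed = 4), counts)
  cfg_bad <- cfg; cfg_bad$mean_depth <- -1
  expect_error(simulate_read_counts(cs, grid, cfg_bad, seed = 1),
               "negative depth")
  expect_error(simulate_read_counts(cs[1:10], grid, cfg), "aligned")
})

test_that("count dispersion matches the stated variance model", {
  # goodness of fit of the standardized residuals at alpha = 0.01
  grid <- flat_grid(n_bins = 10000)
  cfg <- sim_config(genome = small_genome(), gc_bias_strength = 0,
                    dispersion = 0.05, mean_depth = 50)
  counts <- simulate_read_counts(rep(2L, 10000), grid, cfg, seed = 11)
  mu <- 50
  v <- mu + 0.05 * mu^2
  z2 <- sum((counts - mu)^2 / v)
  expect_gt(z2, qchisq(0.005, 10000))
  expect_lt(z2, qchisq(0.995, 10000))
})

test_that("immune counts are calibrated gamma-Poisson draws", {
  cfg <- sim_config()
  imm <- simulate_immune_counts("BRCAm", cfg, seed = 3)
  expect_equal(dim(imm$counts), c(4L, 4L))
  expect_true(all(imm$counts >= 0))

  # zero mean gives all-zero cores
  cfg0 <- cfg
  cfg0$immune_model$mean[] <- 0
  imm0 <- simulate_immune_counts("NSMP", cfg0, seed = 1)
  expect_true(all(imm0$counts == 0))

  # BRCAm configured mean exceeds CCNE1 for every marker
  expect_true(all(cfg$immune_model$mean["BRCAm", ] >
                    cfg$immune_model$mean["CCNE1", ]))

  # empirical mean over 2000 draws within 5% of the configured mean
  mu <- cfg$immune_model$mean["BRCAm", "CD8"]
  draws <- vapply(1:2000, function(s)
    mean(simulate_immune_counts("BRCAm", cfg, seed = s)$counts["CD8", ]), 0)
  expect_lt(abs(mean(draws) - mu) / mu, 0.05)

  cfg_bad <- cfg
  colnames(cfg_bad$immune_model$mean) <- c("CD8", "CD20", "CD68", "CDX")
  expect_error(tri_categorize(5, "CDX"), "arg")
})

test_that("survival draws match the exponential closed form", {
  cfg <- sim_config()
  cfg$survival_model$censor_horizon <- 1e7  # effectively no censoring
  h <- cfg$survival_model$os_hazard["NSMP"] /
    (cfg$survival_model$cd103_p_high["NSMP"] *
       cfg$survival_model$cd103_high_hr +
       1 - cfg$survival_model$cd103_p_high["NSMP"])
  meds <- vapply(1:50000, function(s)
    simulate_survival("NSMP", FALSE, cfg, seed = s)$os_months, 0)
  expect_lt(abs(median(meds) - log(2) / h) / (log(2) / h), 0.02)

  # near-zero horizon: event rate goes to zero
  cfg$survival_model$censor_horizon <- 0.05
  ev <- vapply(1:200, function(s)
    simulate_survival("BRCAm", FALSE, cfg, seed = s)$os_event, 0L)
  expect_equal(sum(ev), 0L)
  cfg$survival_model$censor_horizon <- -1
  expect_error(simulate_survival("BRCAm", FALSE, cfg, seed = 1), "horizon")
})

test_that("cohorts reproduce the configured world deterministically", {
  cfg <- sim_config(seed = 21L)
  sim <- simulate_cohort(cfg, counts = FALSE)
  expect_equal(nrow(sim$roster), 348)

  # truth counts within binomial 99% bounds of the published 105/67/45/69/62
  expected_p <- cfg$profile_proportions
  counts <- table(factor(sim$truth$true_profile, levels = names(expected_p)))
  for (k in names(expected_p)) {
    expect_gte(counts[[k]], qbinom(0.005, 348, expected_p[[k]]))
    expect_lte(counts[[k]], qbinom(0.995, 348, expected_p[[k]]))
  }

  # PFS <= OS for every patient; BRCAm truth iff mutation or methylation
  expect_true(all(sim$roster$pfs_months <= sim$roster$os_months))
  is_brcam <- sim$truth$true_profile == "BRCAm"
  has_event <- sim$truth$brca_mutation != "none" | sim$truth$brca1_methylation
  expect_equal(is_brcam, has_event)
  expect_false(any(sim$truth$brca_mutation != "none" &
                     sim$truth$brca1_methylation))

  # empty cohort and determinism
  e <- simulate_cohort(sim_config(n_patients = 0L), counts = FALSE)
  expect_equal(nrow(e$roster), 0)
  sim2 <- simulate_cohort(sim_config(seed = 21L), counts = FALSE)
  expect_identical(sim$roster, sim2$roster)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(profile_proportions = c(.5, .5, 0, 0, .1)),
               "summing to 1")
  expect_error(sim_config(nonsense_field = 1), "unknown")
  expect_silent(sim_config(mean_depth = 0))
})
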