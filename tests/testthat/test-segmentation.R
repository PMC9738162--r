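# exhaustive arc-search oracle for CBS on small profiles
oracle_best_arc <- function(y, min_width = 2) {
  n <- length(y)
  best <- c(NA, NA, -Inf)
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      m <- j - i
      if (m >= n) next
      arc <- y[(i + 1):j]; rest <- y[-((i + 1):j)]
      sp2 <- (sum((arc - mean(arc))^2) + sum((rest - mean(rest))^2)) /
        max(n - 2, 1)
      t2 <- (mean(arc) - mean(rest))^2 /
        (max(sp2, 1e-12) * (1 / m + 1 / (n - m)))
      if (t2 > best[3]) best <- c(i, j, t2)
    }
  }
  best
}

test_that("the CBS arc scan equals exhaustive search on <= 100 bins", {
  # noiseless step: breakpoint exactly at bin 50
  y <- c(rep(0, 50), rep(1, 50))
  sp <- hgsocmp:::.cbs_best_split(y, 2L, 1000L, 0.01, 7L)
  o <- oracle_best_arc(y)
  expect_equal(c(sp$i, sp$j), o[1:2])
  expect_equal(sort(unique(c(sp$i, sp$j) %% 100)), c(0, 50))
  expect_lt(sp$p, 0.01)

  # random noisy profiles: argmax agrees with the oracle
  set.seed(41)
  for (rep in 1:5) {
    y <- rnorm(60) + rep(c(0, 1.5, 0), c(20, 15, 25))
    sp <- hgsocmp:::.cbs_best_split(y, 2L, 1000L, 0.01, rep)
    o <- oracle_best_arc(y)
    expect_equal(sp$t2, o[3], tolerance = 1e-9)
    expect_equal(c(sp$i, sp$j), o[1:2])
  }
})

test_that("segment_cbs finds constant and step profiles correctly", {
  grid <- flat_grid(n_bins = 200, bin_size = 30000L, chroms = 2L)
  # constant: one segment per chromosome
  prof <- profile_from_ratios(rep(0.1, 200), grid)
  seg <- segment_cbs(prof, seed = 1)
  expect_equal(nrow(seg), 2)
  expect_equal(as.integer(table(seg$chrom)), c(1L, 1L))

  # noiseless step inside chr1
  r <- rep(0, 200); r[51:100] <- 1
  seg2 <- segment_cbs(profile_from_ratios(r, grid), seed = 1)
  ch1 <- seg2[seg2$chrom == "chr1", ]
  expect_equal(nrow(ch1), 2)
  expect_equal(ch1$start[2], grid$start[51])
  expect_equal(sort(ch1$mean_log2), c(0, 1))

  # determinism
  set.seed(42)
  rn <- rnorm(200, sd = 0.3) + rep(c(0, 0.8), each = 100)
  p <- profile_from_ratios(rn, grid)
  expect_identical(segment_cbs(p, seed = 5), segment_cbs(p, seed = 5))
})

test_that("segment means reconstruct the profile mean", {
  set.seed(43)
  grid <- flat_grid(n_bins = 300, bin_size = 30000L, chroms = 3L)
  r <- rnorm(300, sd = 0.25) + rep(c(-0.6, 0, 0.9), each = 100)
  seg <- segment_cbs(profile_from_ratios(r, grid), seed = 2)
  expect_lt(abs(sum(seg$mean_log2 * seg$n_bins) / sum(seg$n_bins) -
                  mean(r)), 1e-9)
  # segments partition the non-missing bins
  expect_equal(sum(seg$n_bins), 300)
})

test_that("30 kb preprocessing removes blacklisted bins and spikes", {
  cfg <- small_config(gc_bias_strength = 0)
  grid <- build_bin_grid(cfg$genome, 30000L, blacklist_frac = 0.02, seed = 6)
  grid$mappability <- 1
  counts <- simulate_read_counts(rep(2L, nrow(grid)), grid, cfg, seed = 2)
  prof <- preprocess_30kb(counts, grid)
  expect_true(all(is.na(prof$log2[grid$blacklist])))

  # single spike among flat bins is removed as an outlier
  counts2 <- rep(80L, nrow(grid))
  counts2[500] <- as.integer(80 * 2^3)
  set.seed(7)
  counts2 <- counts2 + sample(-5:5, nrow(grid), replace = TRUE)
  prof2 <- preprocess_30kb(counts2, grid)
  expect_true(is.na(prof2$log2[500]))

  # clean profiles lose under 1% of usable bins to the outlier rule
  usable <- !grid$blacklist
  lost <- mean(is.na(prof$log2[usable]))
  expect_lt(lost, 0.01)
})

test_that("smoothing only touches noisy profiles and preserves edges", {
  grid <- flat_grid(n_bins = 200, bin_size = 30000L)
  set.seed(44)
  clean <- profile_from_ratios(rnorm(200, sd = 0.1), grid)
  expect_identical(smooth_if_noisy(clean, mapd_threshold = 0.45), clean)

  noisy <- profile_from_ratios(rnorm(200, sd = 0.6), grid)
  sm <- smooth_if_noisy(noisy, mapd_threshold = 0.45)
  expect_lt(sm$noise_mapd, noisy$noise_mapd)

  # a step edge moves by at most half the window
  step <- rnorm(200, sd = 0.6) + rep(c(0, 2), each = 100)
  smp <- smooth_if_noisy(profile_from_ratios(step, grid),
                         mapd_threshold = 0.45, window = 9)
  cross <- which(smp$log2 > 1)[1]
  expect_lte(abs(cross - 101), 4)
})

test_that("state calling recovers well-separated mixtures and falls back", {
  mk_seg <- function(means, n_bins = 40) {
    s <- data.frame(sample_id = "s", chrom = "chr1",
                    start = seq_along(means) * 1e6,
                    end = seq_along(means) * 1e6 + 9e5,
                    start_bin = 1, end_bin = 2, n_bins = n_bins,
                    mean_log2 = means, stringsAsFactors = FALSE)
    s$chrom <- factor(s$chrom)
    class(s) <- c("segmented_profile", "data.frame")
    s
  }
  set.seed(45)
  truth <- sample(1:4, 300, replace = TRUE,
                  prob = c(0.15, 0.6, 0.15, 0.1))
  means <- c(-1, 0, 0.45, 1.3)[truth] + rnorm(300, sd = 0.05)
  seg <- call_states(mk_seg(means))
  expect_equal(as.integer(seg$call), truth)

  # responsibilities match direct Gaussian density evaluation
  fit <- hgsocmp:::fit_cn_mixture(means, rep(40, 300))
  resp <- hgsocmp:::cn_responsibility(means[1:10], fit)
  oracle <- sapply(1:4, function(k)
    fit$pi[k] * dnorm(means[1:10], fit$mu[k], fit$sd[k]))
  oracle <- oracle / rowSums(oracle)
  expect_equal(resp, oracle, tolerance = 1e-12)

  # segment mean 0 is neutral under both routes
  expect_equal(as.character(call_states(mk_seg(c(0, 0.01, -0.02)))$call),
               rep("neutral", 3))
  expect_equal(as.character(hgsocmp:::call_fallback(0)), "neutral")

  # all-neutral genome: no gain or amplification calls (fallback path)
  seg0 <- call_states(mk_seg(rnorm(50, 0, 0.03)))
  expect_true(all(seg0$call == "neutral"))
})

test_that("CCNE1 status applies half-open overlap and call precedence", {
  seg <- data.frame(
    sample_id = "s", chrom = factor(rep("chr19", 3)),
    start = c(0, 3e6, 3.2e6), end = c(3e6, 3.2e6, 7e6),
    start_bin = NA, end_bin = NA, n_bins = c(100, 7, 120),
    mean_log2 = c(0, 0.5, 0.01), stringsAsFactors = FALSE)
  class(seg) <- c("segmented_profile", "data.frame")
  locus <- list(chrom = "chr19", start = 3e6, end = 3.4e6)

  seg$call <- factor(c("neutral", "neutral", "neutral"),
                     levels = hgsocmp:::CALL_STATES)
  expect_equal(ccne1_status(seg, locus)$status, "none")

  seg$call <- factor(c("neutral", "gain", "neutral"),
                     levels = hgsocmp:::CALL_STATES)
  expect_equal(ccne1_status(seg, locus)$status, "gain")

  seg$call <- factor(c("neutral", "gain", "amplification"),
                     levels = hgsocmp:::CALL_STATES)
  expect_equal(ccne1_status(seg, locus)$status, "amplification")

  # a segment ending exactly at the locus start does not overlap (half-open)
  seg$call <- factor(c("amplification", "neutral", "neutral"),
                     levels = hgsocmp:::CALL_STATES)
  seg$end[1] <- 3e6
  expect_equal(ccne1_status(seg, locus)$status, "none")

  expect_error(ccne1_status(seg, list(chrom = "chrZ", start = 0, end = 1)),
               "not present")
})

test_that("a focal synthetic amplicon is recovered end-to-end from counts", {
  cfg <- small_config()
  grid <- build_bin_grid(cfg$genome, 30000L, seed = 9)
  segs <- data.frame(chrom = "chr19", start = 2.9e6, end = 3.6e6, copy = 6L)
  counts <- simulate_read_counts(project_copy_states(segs, grid), grid, cfg,
                                 seed = 10)
  prof <- smooth_if_noisy(preprocess_30kb(counts, grid))
  called <- call_states(segment_cbs(prof, seed = 11))
  expect_equal(ccne1_status(called, cfg$ccne1_locus)$status, "amplification")
})

test_that("calling is invariant to chromosome ordering", {
  set.seed(46)
  grid <- flat_grid(n_bins = 200, bin_size = 30000L, chroms = 2L)
  r <- rnorm(200, sd = 0.2) + rep(c(0, 0.9), each = 100)
  seg <- call_states(segment_cbs(profile_from_ratios(r, grid), seed = 3))
  # reverse chromosome order
  grid2 <- grid[c(101:200, 1:100), ]
  grid2$chrom <- factor(as.character(grid2$chrom),
                        levels = c("chr2", "chr1"))
  seg2 <- call_states(segment_cbs(
    profile_from_ratios(r[c(101:200, 1:100)], grid2), seed = 3))
  key <- function(s) s[order(as.character(s$chrom), s$start),
                       c("start", "end", "n_bins", "mean_log2", "call")]
  k1 <- key(seg); k2 <- key(seg2)
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})
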