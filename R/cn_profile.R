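#' Count aligned reads into grid bins
#'
#' Optional read-level entry point: each read is assigned to the bin
#' containing its leftmost aligned base (0-based, half-open bins); reads
#' with mapping quality strictly greater than `mapq_threshold` are counted.
#' Reads on chromosomes absent from the grid are tallied as rejects, not
#' errors.
#'
#' @param reads data.frame with columns `chrom`, `pos` (0-based leftmost
#'   base), `mapq`
#' @param grid a `bin_grid`
#' @param mapq_threshold integer; reads must exceed it (default 15)
#' @return integer per-bin counts with attribute `n_rejected`
#' @export
bin_reads <- function(reads, grid, mapq_threshold = 15L) {
  stopifnot(all(c("chrom", "pos", "mapq") %in% names(reads)))
  counts <- integer(nrow(grid))
  keep <- reads$mapq > mapq_threshold
  reads <- reads[keep, , drop = FALSE]
  known <- reads$chrom %in% levels(grid$chrom)
  n_rejected <- sum(!known)
  reads <- reads[known, , drop = FALSE]
  for (ch in unique(reads$chrom)) {
    gi <- which(grid$chrom == ch)
    pos <- reads$pos[reads$chrom == ch]
    idx <- findInterval(pos, grid$start[gi])
    ok <- idx >= 1L & pos < grid$end[gi][pmax(idx, 1L)]
    tb <- tabulate(idx[ok], nbins = length(gi))
    counts[gi] <- counts[gi] + tb
    n_rejected <- n_rejected + sum(!ok)
  }
  structure(counts, n_rejected = n_rejected)
}

usable_bins <- function(counts, grid) {
  !grid$blacklist & !is.na(counts) & counts > 0
}

#' Correct binned counts for GC bias
#'
#' Divides each bin's count by a lowess-smoothed median count per GC value
#' (span 0.3), fitted on non-blacklisted, nonzero bins, and rescales so the
#' overall median count is preserved. This is the standard shallow-WGS
#' correction: after it, counts should be uncorrelated with GC.
#'
#' @param counts numeric per-bin counts
#' @param grid a `bin_grid`
#' @param span lowess span (default 0.3)
#' @return corrected counts (same length; blacklisted bins untouched)
#' @export
correct_gc <- function(counts, grid, span = 0.3) {
  use <- usable_bins(counts, grid)
  if (sum(use) < 100) stopf("fewer than 100 usable bins")
  if (all(counts[use] == 0)) stopf("empty profile")
  gc_strat <- round(grid$gc[use], 2)
  med <- tapply(counts[use], gc_strat, stats::median)
  gc_vals <- as.numeric(names(med))
  fit <- stats::lowess(gc_vals, med, f = span)
  pred <- stats::approx(fit$x, fit$y, xout = grid$gc, rule = 2)$y
  pred[pred <= 0] <- NA
  corrected <- counts / pred * stats::median(counts[use])
  corrected[grid$blacklist] <- counts[grid$blacklist]
  corrected
}

#' Correct binned counts for mappability
#'
#' Divides counts by per-bin mappability; bins with mappability below
#' `min_mappability` are set missing.
#'
#' @inheritParams correct_gc
#' @param min_mappability bins below this are unusable (default 0.2)
#' @return corrected counts with low-mappability bins `NA`
#' @export
correct_mappability <- function(counts, grid, min_mappability = 0.2) {
  stopifnot(all(grid$mappability >= 0 & grid$mappability <= 1))
  corrected <- counts / grid$mappability
  corrected[grid$mappability < min_mappability] <- NA
  corrected
}

#' Convert corrected counts to a log2 ratio profile
#'
#' `ratio = log2(count / median(corrected counts))` over usable bins,
#' recentered so the median of non-missing ratios is exactly zero.
#' Zero-count and blacklisted bins are missing. The profile carries a MAPD
#' noise metric (median absolute difference of successive ratios within
#' chromosomes) and a QC flag (`noise_mapd < qc_threshold`).
#'
#' @param counts corrected per-bin counts
#' @param grid a `bin_grid`
#' @param sample_id sample label
#' @param qc_threshold MAPD above which the profile fails automated QC
#'   (default 0.6, for 20 kb bins)
#' @return a `ratio_profile`: list with `sample_id`, `grid`, `log2`,
#'   `noise_mapd`, `qc_pass`
#' @export
to_log2_ratios <- function(counts, grid, sample_id = "sample",
                           qc_threshold = 0.6) {
  ratio <- rep(NA_real_, nrow(grid))
  use <- !grid$blacklist & !is.na(counts) & counts > 0
  med <- stats::median(counts[use])
  if (!isTRUE(med > 0)) stopf("profile median is zero")
  ratio[use] <- log2(counts[use] / med)
  ratio <- ratio - stats::median(ratio, na.rm = TRUE)
  nm <- mapd(ratio, grid$chrom)
  structure(list(sample_id = sample_id, grid = grid, log2 = ratio,
                 noise_mapd = nm,
                 qc_pass = !is.na(nm) && nm < qc_threshold),
            class = "ratio_profile")
}

#' Full 20 kb correction pipeline for one sample
#'
#' GC correction, mappability correction, then log2 ratios; the standard
#' order of operations for shallow-WGS profiles.
#' @inheritParams to_log2_ratios
#' @export
make_ratio_profile <- function(counts, grid, sample_id = "sample",
                               qc_threshold = 0.6) {
  cc <- correct_gc(counts, grid)
  cc <- correct_mappability(cc, grid)
  to_log2_ratios(cc, grid, sample_id, qc_threshold)
}

#' Aggregate a 20 kb ratio profile to 1 MB resolution
#'
#' Each 1 MB bin is the mean of its non-missing constituent 20 kb ratios and
#' is missing when fewer than `min_frac` of its constituents are present.
#'
#' @param profile a 20 kb `ratio_profile`
#' @param out_bin_size aggregated bin width (default 1e6)
#' @param min_frac minimum fraction of non-missing constituents (default
#'   0.5)
#' @return a `ratio_profile` on the aggregated grid (no annotation columns
#'   beyond coordinates)
#' @export
aggregate_to_1mb <- function(profile, out_bin_size = 1e6, min_frac = 0.5) {
  grid <- profile$grid
  bs <- attr(grid, "bin_size") %||% max(grid$end - grid$start)
  if (out_bin_size %% bs != 0 && out_bin_size < bs)
    stopf("aggregation bin size must exceed source bin size")
  key <- paste(grid$chrom, floor(grid$start / out_bin_size), sep = ":")
  key <- factor(key, levels = unique(key))
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  n_tot <- as.numeric(tapply(rep(1, nrow(grid)), key, sum))
  n_ok <- as.numeric(tapply(!is.na(profile$log2), key, sum))
  mean_r <- as.numeric(tapply(profile$log2, key,
                              function(v) mean(v, na.rm = TRUE)))
  mean_r[n_ok / n_tot < min_frac | n_ok == 0] <- NA
  out_grid <- data.frame(
    chrom = factor(sub(":.*", "", levels(key)),
                   levels = levels(grid$chrom)),
    start = as.numeric(sub(".*:", "", levels(key))) * out_bin_size)
  out_grid$end <- pmin(out_grid$start + out_bin_size,
                       as.numeric(tapply(grid$end, key, max)))
  out_grid$gc <- agg(grid$gc, mean)
  out_grid$mappability <- agg(grid$mappability, mean)
  out_grid$blacklist <- FALSE
  class(out_grid) <- c("bin_grid", "data.frame")
  attr(out_grid, "bin_size") <- as.integer(out_bin_size)
  structure(list(sample_id = profile$sample_id, grid = out_grid,
                 log2 = mean_r, noise_mapd = mapd(mean_r, out_grid$chrom),
                 qc_pass = profile$qc_pass),
            class = "ratio_profile")
}

#' Fit the cross-platform centering/scaling calibration
#'
#' Computes the location-wise (per-bin) average ratio across samples within
#' the training set and within the current set, sorts each average vector
#' ascending, and regresses the sorted training vector on the sorted
#' current vector by ordinary least squares. The intercept corrects
#' centering, the slope corrects scaling; applying
#' `alpha + beta * ratio` maps current data onto the training scale.
#'
#' @param training matrix (bins x samples) of training-set log2 ratios
#' @param current matrix (bins x samples) of current-set log2 ratios on the
#'   same grid
#' @return list with `alpha` and `beta`
#' @export
fit_calibration <- function(training, current) {
  training <- as.matrix(training); current <- as.matrix(current)
  if (nrow(training) != nrow(current)) stopf("calibration grids differ")
  if (ncol(training) < 2 || ncol(current) < 2)
    stopf("need >= 2 samples per set")
  tr <- sort(rowMeans(training, na.rm = TRUE))
  cu <- sort(rowMeans(current, na.rm = TRUE))
  n <- min(length(tr), length(cu))
  # sorted vectors compared at matching quantiles
  q <- (seq_len(n) - 0.5) / n
  tr <- stats::quantile(tr, q, names = FALSE, type = 7)
  cu <- stats::quantile(cu, q, names = FALSE, type = 7)
  if (stats::sd(cu) < 1e-12) stopf("calibration underdetermined")
  beta <- stats::cov(cu, tr) / stats::var(cu)
  alpha <- mean(tr) - beta * mean(cu)
  if (beta <= 0) stopf("calibration slope not positive")
  list(alpha = alpha, beta = beta)
}

#' Apply a calibration model to a ratio profile or matrix
#'
#' @param x a `ratio_profile` or numeric matrix/vector of log2 ratios
#' @param model list with `alpha`, `beta` from [fit_calibration()]
#' @return object of the same shape with `alpha + beta * ratio`
#' @export
apply_calibration <- function(x, model) {
  if (inherits(x, "ratio_profile")) {
    x$log2 <- model$alpha + model$beta * x$log2
    return(x)
  }
  model$alpha + model$beta * x
}

#' Write / read a ratio profile as TSV
#'
#' Columns chrom, start, end, log2_ratio with NA for missing bins.
#' @param profile a `ratio_profile`
#' @param path file path
#' @export
write_ratio_profile <- function(profile, path) {
  df <- data.frame(chrom = profile$grid$chrom, start = profile$grid$start,
                   end = profile$grid$end, log2_ratio = profile$log2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratio_profile
#' @param sample_id sample label for the profile read back
#' @export
read_ratio_profile <- function(path, sample_id = "sample") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  grid <- data.frame(chrom = factor(df$chrom, levels = unique(df$chrom)),
                     start = df$start, end = df$end, gc = NA_real_,
                     mappability = 1, blacklist = FALSE)
  class(grid) <- c("bin_grid", "data.frame")
  attr(grid, "bin_size") <- as.integer(max(df$end - df$start))
  structure(list(sample_id = sample_id, grid = grid, log2 = df$log2_ratio,
                 noise_mapd = mapd(df$log2_ratio, grid$chrom),
                 qc_pass = TRUE),
            class = "ratio_profile")
}
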