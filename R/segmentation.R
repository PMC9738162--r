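#' Preprocess 30 kb binned counts for segmentation
#'
#' The CCNE1-calling arm of the pipeline: blacklisted bins removed (missing
#' in the output), GC and mappability correction, log2 normalization, and
#' outlier removal — bins whose ratio deviates from a running median
#' (window 5, per chromosome) by more than `outlier_k` times the profile
#' MAPD are set missing.
#'
#' @param counts per-bin counts on a 30 kb grid
#' @param grid a `bin_grid`
#' @param sample_id sample label
#' @param outlier_k outlier threshold in MAPD units (default 4)
#' @param qc_threshold MAPD QC threshold for the ratio profile
#' @return a `ratio_profile`
#' @export
preprocess_30kb <- function(counts, grid, sample_id = "sample",
                            outlier_k = 4, qc_threshold = 0.6) {
  prof <- make_ratio_profile(counts, grid, sample_id, qc_threshold)
  r <- prof$log2
  nm <- prof$noise_mapd
  for (ch in levels(grid$chrom)) {
    idx <- which(grid$chrom == ch & !is.na(r))
    if (length(idx) < 5) next
    rm5 <- stats::runmed(r[idx], k = 5, endrule = "median")
    out <- abs(r[idx] - rm5) > outlier_k * nm
    r[idx[out]] <- NA
  }
  prof$log2 <- r
  prof$noise_mapd <- mapd(r, grid$chrom)
  prof
}

#' Smooth a ratio profile only if it is noisy
#'
#' Profiles whose MAPD exceeds `mapd_threshold` are replaced by a centered
#' rolling median (window `window`, per chromosome over non-missing bins);
#' clean profiles are returned untouched, retaining unbiased segmentation
#' in high-quality data.
#'
#' @param profile a `ratio_profile`
#' @param mapd_threshold MAPD above which smoothing kicks in (default 0.45
#'   at 30 kb)
#' @param window rolling-median window (odd, default 9)
#' @return a `ratio_profile`
#' @export
smooth_if_noisy <- function(profile, mapd_threshold = 0.45, window = 9) {
  if (is.na(profile$noise_mapd) || profile$noise_mapd <= mapd_threshold)
    return(profile)
  r <- profile$log2
  for (ch in levels(profile$grid$chrom)) {
    idx <- which(profile$grid$chrom == ch & !is.na(r))
    if (length(idx) < window) next
    r[idx] <- stats::runmed(r[idx], k = window, endrule = "median")
  }
  profile$log2 <- r
  profile$noise_mapd <- mapd(r, profile$grid$chrom)
  profile
}

cbs_recurse <- function(y, alpha, n_perm, min_width, seed) {
  n <- length(y)
  if (n < 2 * min_width) return(list(seq_len(n)))
  sp <- .cbs_best_split(y, as.integer(min_width), as.integer(n_perm),
                        alpha, as.integer(seed %% 2147483647))
  if (sp$i < 0 || sp$p >= alpha) return(list(seq_len(n)))
  i <- sp$i; j <- sp$j
  pieces <- list()
  if (i > 0) pieces <- c(pieces, list(seq_len(i)))
  pieces <- c(pieces, list(seq.int(i + 1, j)))
  if (j < n) pieces <- c(pieces, list(seq.int(j + 1, n)))
  out <- list()
  for (k in seq_along(pieces)) {
    idx <- pieces[[k]]
    sub <- cbs_recurse(y[idx], alpha, n_perm, min_width,
                       derive_seed(seed, paste0("s", k)))
    out <- c(out, lapply(sub, function(s) idx[s]))
  }
  out
}

#' Circular binary segmentation of a ratio profile
#'
#' Recursive CBS: on each current segment, the two-sample t statistic
#' between every circular arc and its complement is maximized exhaustively;
#' the best split is accepted when its permutation p-value is below `alpha`
#' and recursion continues on the pieces. Adjacent segments whose means
#' differ by less than `merge_threshold` are merged afterwards. Missing
#' bins do not break segments; each chromosome is segmented over its
#' non-missing bins.
#'
#' @param profile a `ratio_profile`
#' @param alpha significance level for a split (default 0.01)
#' @param n_perm permutations per split test (default 1000)
#' @param min_width minimum segment width in bins (default 2)
#' @param merge_threshold merge adjacent segments closer than this in mean
#'   log2 (default 0.1)
#' @param seed integer seed for the permutations
#' @return a `segmented_profile`: data.frame (sample_id, chrom, start, end,
#'   start_bin, end_bin, n_bins, mean_log2)
#' @export
segment_cbs <- function(profile, alpha = 0.01, n_perm = 1000,
                        min_width = 2, merge_threshold = 0.1,
                        seed = 1L) {
  grid <- profile$grid
  segs <- list()
  for (ch in levels(grid$chrom)) {
    idx <- which(grid$chrom == ch & !is.na(profile$log2))
    if (!length(idx)) next
    y <- profile$log2[idx]
    parts <- cbs_recurse(y, alpha, n_perm, min_width,
                         derive_seed(seed, ch))
    means <- vapply(parts, function(s) mean(y[s]), 0)
    # merge adjacent segments with close means
    k <- 1L
    while (k < length(parts)) {
      if (abs(means[k + 1] - means[k]) < merge_threshold) {
        parts[[k]] <- c(parts[[k]], parts[[k + 1]])
        means[k] <- mean(y[parts[[k]]])
        parts[[k + 1]] <- NULL
        means <- means[-(k + 1)]
      } else k <- k + 1L
    }
    for (k in seq_along(parts)) {
      s <- parts[[k]]
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = profile$sample_id, chrom = ch,
        start = grid$start[idx[min(s)]], end = grid$end[idx[max(s)]],
        start_bin = idx[min(s)], end_bin = idx[max(s)],
        n_bins = length(s), mean_log2 = means[k],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  out$chrom <- factor(out$chrom, levels = levels(grid$chrom))
  class(out) <- c("segmented_profile", "data.frame")
  out
}

CALL_STATES <- c("loss", "neutral", "gain", "amplification")
FALLBACK_CUTS <- c(-0.25, 0.25, 0.85)

call_fallback <- function(means) {
  cut(means, breaks = c(-Inf, FALLBACK_CUTS, Inf), labels = CALL_STATES)
}

#' Call discrete copy-number states on segmented profiles
#'
#' Fits a four-component one-dimensional Gaussian mixture
#' (loss < neutral < gain < amplification, neutral anchored near zero) to
#' the bin-weighted segment means by EM, then assigns each segment its
#' maximum-responsibility state. Calling may pool several samples'
#' segments for a stable fit. When a component empties, the means
#' disorder, or EM fails to converge, fixed log2 thresholds
#' (-0.25 / 0.25 / 0.85) are used instead.
#'
#' @param segmented a `segmented_profile` or list of them (pooled fit,
#'   per-segment calls returned in the same structure)
#' @param max_iter EM iteration cap (default 500)
#' @param seed seed (kept for interface stability; the fit is
#'   deterministic given its fixed initialization)
#' @return input with a `call` factor column added
#' @export
call_states <- function(segmented, max_iter = 500, seed = 1L) {
  single <- inherits(segmented, "segmented_profile")
  seg_list <- if (single) list(segmented) else segmented
  all_means <- unlist(lapply(seg_list, `[[`, "mean_log2"))
  all_w <- unlist(lapply(seg_list, `[[`, "n_bins"))
  fit <- fit_cn_mixture(all_means, all_w, max_iter = max_iter)
  assign_calls <- function(seg) {
    seg$call <- if (is.null(fit)) call_fallback(seg$mean_log2) else
      factor(CALL_STATES[apply(cn_responsibility(seg$mean_log2, fit), 1,
                               which.max)], levels = CALL_STATES)
    seg
  }
  seg_list <- lapply(seg_list, assign_calls)
  if (single) seg_list[[1]] else seg_list
}

# EM for the constrained 4-component mixture; returns NULL when the
# fallback thresholds should be used instead.
fit_cn_mixture <- function(means, weights, max_iter = 500, tol = 1e-8) {
  if (length(means) < 5) return(NULL)
  mu <- c(-1, 0, 0.585, 1.32)
  sdv <- rep(0.15, 4)
  # k-means-style seeded init: assign to nearest initial mean
  init <- apply(abs(outer(means, mu, "-")), 1, which.min)
  pi_k <- pmax(tabulate(init, 4) / length(means), 1e-3)
  pi_k <- pi_k / sum(pi_k)
  w <- weights / mean(weights)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- sapply(1:4, function(k)
      pi_k[k] * stats::dnorm(means, mu[k], sdv[k]))
    tot <- rowSums(dens)
    if (any(tot <= 0)) return(NULL)
    resp <- dens / tot
    ll <- sum(w * log(tot))
    nk <- colSums(w * resp)
    if (any(nk < 1e-4)) return(NULL)  # empty component
    pi_k <- nk / sum(nk)
    mu_new <- colSums(w * resp * means) / nk
    mu_new[2] <- max(-0.1, min(0.1, mu_new[2]))  # anchor neutral near 0
    if (is.unsorted(mu_new)) return(NULL)
    mu <- mu_new
    sdv <- sqrt(pmax(colSums(w * resp * outer(means, mu, "-")^2) / nk,
                     4e-4))
    if (abs(ll - ll_old) < tol) {
      return(list(mu = mu, sd = sdv, pi = pi_k))
    }
    ll_old <- ll
  }
  warning("copy-number mixture EM did not converge; using fixed thresholds")
  NULL
}

cn_responsibility <- function(means, fit) {
  dens <- sapply(1:4, function(k)
    fit$pi[k] * stats::dnorm(means, fit$mu[k], fit$sd[k]))
  dens <- matrix(dens, ncol = 4)
  dens / pmax(rowSums(dens), .Machine$double.xmin)
}

#' CCNE1 locus status from a called segmented profile
#'
#' Collects the segments overlapping the locus (half-open interval overlap)
#' and reports `amplification` if any overlapping segment is called
#' amplification, else `gain` if any is called gain, else `none`.
#'
#' @param segmented a `segmented_profile` with calls
#' @param locus list with `chrom`, `start`, `end`
#' @return list: `sample_id`, `status`, `supporting_segment` (row or NULL)
#' @export
ccne1_status <- function(segmented, locus) {
  if (!locus$chrom %in% levels(segmented$chrom) &&
      !locus$chrom %in% as.character(segmented$chrom))
    stopf("locus chromosome %s not present", locus$chrom)
  ov <- segmented[as.character(segmented$chrom) == locus$chrom &
                    segmented$start < locus$end &
                    segmented$end > locus$start, , drop = FALSE]
  status <- "none"; supporting <- NULL
  if (nrow(ov)) {
    if (any(ov$call == "amplification")) {
      status <- "amplification"
      supporting <- ov[ov$call == "amplification", ][1, ]
    } else if (any(ov$call == "gain")) {
      status <- "gain"
      supporting <- ov[ov$call == "gain", ][1, ]
    }
  }
  list(sample_id = segmented$sample_id[1], status = status,
       supporting_segment = supporting)
}

#' Write / read segments as SEG-format TSV
#'
#' Columns: sample, chrom, start, end, n_bins, mean_log2, call.
#' @param segmented a `segmented_profile` (or rbind of several)
#' @param path file path
#' @export
write_seg <- function(segmented, path) {
  df <- data.frame(sample = segmented$sample_id, chrom = segmented$chrom,
                   start = segmented$start, end = segmented$end,
                   n_bins = segmented$n_bins,
                   mean_log2 = segmented$mean_log2,
                   call = if ("call" %in% names(segmented))
                     as.character(segmented$call) else NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- data.frame(sample_id = df$sample, chrom = factor(df$chrom),
                    start = df$start, end = df$end,
                    start_bin = NA_integer_, end_bin = NA_integer_,
                    n_bins = df$n_bins, mean_log2 = df$mean_log2,
                    stringsAsFactors = FALSE)
  if (!all(is.na(df$call)))
    out$call <- factor(df$call, levels = CALL_STATES)
  class(out) <- c("segmented_profile", "data.frame")
  out
}
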