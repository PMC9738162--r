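HRD_LIKE_PROFILES <- c("nonBRCAmutHRD", "double")
CCNE1_PROFILES <- c("CCNE1", "double")

#' Simulate the copy-number segment structure for one tumor genome
#'
#' Produces a list of altered segments on the configured genome; the
#' untouched background is copy 2. Quiet genomes (NSMP, and a configurable
#' fraction of BRCA-mutated tumors) carry at most a couple of scattered
#' alterations; HRD-like genomes carry recurrent signature regions (fixed
#' location and direction, each altered independently) plus many scattered
#' copy 1/3 segments; CCNE1-positive genomes additionally carry one focal
#' amplicon overlapping the configured CCNE1 locus.
#'
#' @param true_profile one of `BRCAm`, `nonBRCAmutHRD`, `CCNE1`, `double`,
#'   `NSMP`
#' @param config a [sim_config()]
#' @param seed integer seed
#' @return data.frame (chrom, start, end, copy) of altered segments, with
#'   attributes `hrd_like` (logical) and `ccne1_truth`
#'   (none/gain/amplification)
#' @export
simulate_cn_segments <- function(true_profile, config, seed = config$seed) {
  true_profile <- match.arg(true_profile, PROFILES)
  genome <- config$genome
  with_seed(seed, {
    s_chrom <- character(0); s_start <- numeric(0); s_end <- numeric(0)
    s_copy <- integer(0)
    add_seg <- function(chrom, start, end, copy) {
      ov <- s_chrom == chrom & s_start < end & s_end > start
      if (any(ov)) return(FALSE)
      s_chrom[length(s_chrom) + 1L] <<- chrom
      s_start[length(s_start) + 1L] <<- start
      s_end[length(s_end) + 1L] <<- end
      s_copy[length(s_copy) + 1L] <<- as.integer(copy)
      TRUE
    }
    hrd_like <- true_profile %in% HRD_LIKE_PROFILES ||
      (true_profile == "BRCAm" && stats::runif(1) < config$brca_hrd_fraction)
    ccne1_truth <- "none"
    # reserve the CCNE1 locus (with a margin) so background alterations in
    # non-CCNE1 genomes cannot fake a locus gain: truth labels stay exclusive
    if (!true_profile %in% CCNE1_PROFILES) {
      loc <- config$ccne1_locus
      s_chrom <- loc$chrom; s_start <- loc$start - 5e5
      s_end <- loc$end + 5e5; s_copy <- 2L
    }

    if (true_profile %in% CCNE1_PROFILES) {
      loc <- config$ccne1_locus
      clen <- genome$length[match(loc$chrom, genome$chrom)]
      len <- stats::runif(1, config$amp_len_range[1], config$amp_len_range[2])
      min_ov <- min(1e5, len / 2, (loc$end - loc$start) / 2)
      lo <- max(0, loc$start - len + min_ov)
      hi <- min(clen - len, loc$end - min_ov)
      start <- round(stats::runif(1, lo, max(lo, hi)))
      amp <- stats::runif(1) < config$p_amplification
      rng <- if (amp) config$amp_copy_range else config$gain_copy_range
      add_seg(loc$chrom, start, start + round(len),
              sample(seq.int(rng[1], rng[2]), 1))
      ccne1_truth <- if (amp) "amplification" else "gain"
    }

    if (hrd_like) {
      reg <- config$hrd_signature$regions
      for (i in seq_len(nrow(reg))) {
        if (stats::runif(1) < config$hrd_signature$rec_prob)
          add_seg(reg$chrom[i], reg$start[i], reg$end[i],
                  if (reg$direction[i] == "loss") 1L else 3L)
      }
      nr <- config$hrd_signature$n_scatter_range
      n_scatter <- sample(seq.int(nr[1], nr[2]), 1)
      lr <- config$hrd_signature$scatter_len_range
    } else {
      nr <- config$nsmp_n_range
      n_scatter <- if (nr[2] > nr[1]) sample(seq.int(nr[1], nr[2]), 1) else nr[1]
      lr <- config$hrd_signature$scatter_len_range
    }
    if (n_scatter > 0) {
      for (k in seq_len(n_scatter)) {
        for (try in 1:50) {
          ci <- sample.int(nrow(genome), 1, prob = genome$length)
          len <- stats::runif(1, lr[1], min(lr[2], genome$length[ci]))
          start <- round(stats::runif(1, 0, genome$length[ci] - len))
          if (add_seg(genome$chrom[ci], start, start + round(len),
                      sample(c(1L, 3L), 1))) break
        }
      }
    }
    keep <- s_copy != 2L  # drop the copy-neutral locus reservation
    structure(data.frame(chrom = s_chrom[keep], start = s_start[keep],
                         end = s_end[keep], copy = s_copy[keep],
                         stringsAsFactors = FALSE),
              hrd_like = hrd_like, ccne1_truth = ccne1_truth)
  })
}

#' Project altered segments onto a bin grid as per-bin integer copies
#'
#' A bin takes the copy number of the segment covering its midpoint;
#' uncovered bins are copy 2.
#'
#' @param segments data.frame from [simulate_cn_segments()]
#' @param grid a `bin_grid`
#' @return integer vector of per-bin copies
#' @export
project_copy_states <- function(segments, grid) {
  copy <- rep(2L, nrow(grid))
  mid <- (grid$start + grid$end) / 2
  for (i in seq_len(nrow(segments))) {
    hit <- grid$chrom == segments$chrom[i] & mid >= segments$start[i] &
      mid < segments$end[i]
    copy[hit] <- segments$copy[i]
  }
  copy
}

#' Simulate per-bin copy states for one tumor
#'
#' Convenience wrapper: [simulate_cn_segments()] projected onto `grid` via
#' [project_copy_states()]; attributes `hrd_like` and `ccne1_truth` are
#' carried over.
#' @inheritParams simulate_cn_segments
#' @param grid a `bin_grid`
#' @export
simulate_copy_states <- function(true_profile, grid, config,
                                 seed = config$seed) {
  segs <- simulate_cn_segments(true_profile, config, seed)
  structure(project_copy_states(segs, grid),
            hrd_like = attr(segs, "hrd_like"),
            ccne1_truth = attr(segs, "ccne1_truth"))
}

gc_bias_curve <- function(gc, strength, optimum = 0.45) {
  exp(-strength * (gc - optimum)^2)
}

#' Simulate binned read counts from per-bin copy states
#'
#' Counts are negative binomial around
#' `mean_depth * mappability * (copy / 2) * g(GC)` where `g` is a smooth
#' unimodal GC bias curve (`exp(-strength * (gc - optimum)^2)`), with
#' overdispersion `phi` (`Var = mu + phi * mu^2`; `phi = 0` gives Poisson).
#' Blacklisted bins are emitted like any other (the flag lives on the grid).
#'
#' @param copy_states integer vector aligned to `grid`
#' @param grid a `bin_grid`
#' @param config a [sim_config()]
#' @param seed integer seed
#' @return integer vector of per-bin counts
#' @export
simulate_read_counts <- function(copy_states, grid, config,
                                 seed = config$seed) {
  if (length(copy_states) != nrow(grid))
    stopf("copy_states not aligned to grid")
  if (config$mean_depth < 0) stopf("negative depth")
  mu <- config$mean_depth * grid$mappability * (copy_states / 2) *
    gc_bias_curve(grid$gc, config$gc_bias_strength, config$gc_optimum)
  with_seed(seed, {
    if (config$dispersion <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
  })
}

#' Simulate per-marker immune counts over four TMA cores
#'
#' For each marker the patient draws a core-level mean from a gamma
#' distribution (profile-specific shape and mean), then each core count is
#' Poisson around that mean; a small fraction of cores carries no tumor
#' tissue and is flagged for exclusion downstream.
#'
#' @inheritParams simulate_cn_segments
#' @return list with `counts` (markers x cores integer matrix) and
#'   `has_tumor` (logical per core)
#' @export
simulate_immune_counts <- function(true_profile, config,
                                   seed = config$seed) {
  true_profile <- match.arg(true_profile, PROFILES)
  im <- config$immune_model
  if (!true_profile %in% rownames(im$mean))
    stopf("immune_model undefined for profile %s", true_profile)
  markers <- colnames(im$mean)
  nc <- im$n_cores
  with_seed(seed, {
    counts <- matrix(0L, length(markers), nc,
                     dimnames = list(markers, paste0("core", seq_len(nc))))
    for (m in markers) {
      mu <- im$mean[true_profile, m]
      if (mu > 0) {
        lam <- stats::rgamma(1, shape = im$shape[true_profile, m],
                             scale = mu / im$shape[true_profile, m])
        counts[m, ] <- stats::rpois(nc, lam)
      }
    }
    has_tumor <- stats::runif(nc) >= im$p_core_no_tumor
    if (!any(has_tumor)) has_tumor[sample.int(nc, 1)] <- TRUE
    list(counts = counts, has_tumor = has_tumor)
  })
}

#' Simulate overall and progression-free survival for one patient
#'
#' Latent death time is exponential with the profile's baseline hazard times
#' a CD103-density multiplier (normalized to mean one within each profile so
#' profile-level hazards stay anchored); latent progression time is an
#' independent exponential; PFS is the first of progression or death.
#' Administrative censoring is uniform on `(0, horizon)` months. Times are
#' reported at 0.1-month resolution with a floor of 0.1.
#'
#' @inheritParams simulate_cn_segments
#' @param cd103_high logical: per-tumor maximum CD103 count above the
#'   dichotomy cutoff
#' @return list with `os_months`, `os_event`, `pfs_months`, `pfs_event`,
#'   `true_hazard`
#' @export
simulate_survival <- function(true_profile, cd103_high, config,
                              seed = config$seed) {
  true_profile <- match.arg(true_profile, PROFILES)
  sm <- config$survival_model
  if (sm$censor_horizon <= 0) stopf("censoring horizon must be > 0")
  h0 <- sm$os_hazard[true_profile]
  r <- sm$cd103_high_hr
  p <- sm$cd103_p_high[true_profile]
  mult <- (if (isTRUE(cd103_high)) r else 1) / (p * r + (1 - p))
  h_os <- h0 * mult
  h_prog <- log(2) / sm$pfs_median[true_profile] - h0
  if (h_prog <= 0) stopf("pfs hazard not larger than os hazard for %s",
                         true_profile)
  with_seed(seed, {
    t_death <- stats::rexp(1, h_os)
    t_prog <- stats::rexp(1, h_prog)
    cens <- stats::runif(1, 0, sm$censor_horizon)
    t_pfs <- min(t_prog, t_death)
    list(os_months = max(0.1, round(min(t_death, cens), 1)),
         os_event = as.integer(t_death <= cens),
         pfs_months = max(0.1, round(min(t_pfs, cens), 1)),
         pfs_event = as.integer(t_pfs <= cens),
         true_hazard = unname(h_os))
  })
}

draw_cat <- function(tab, profile) {
  p <- tab[profile, ]
  sample(colnames(tab), 1, prob = p / sum(p))
}

#' Simulate a full synthetic cohort
#'
#' Draws truth profiles from the configured proportions, then per patient
#' (with a child seed derived from the master seed and the patient id) the
#' copy-number genome, immune counts, clinical covariates and survival.
#' BRCA-mutation subtype and promoter-methylation flags are drawn at the
#' published within-profile composition, so the BRCAm truth is always
#' mutation or methylation (never both).
#'
#' @param config a [sim_config()]
#' @param counts if `TRUE`, also generate binned read-count matrices on the
#'   20 kb and 30 kb grids (the expensive part); `FALSE` gives a
#'   roster-only cohort for immune/survival work
#' @return list with `roster` (data.frame of patient records before
#'   molecular calling), `truth` (data.frame of truth records),
#'   `immune` (list per patient), and when `counts` is `TRUE`: `grid20`,
#'   `grid30`, `counts20`, `counts30` (bins x samples integer matrices)
#' @export
simulate_cohort <- function(config = sim_config(), counts = TRUE) {
  n <- config$n_patients
  ids <- if (n > 0) sprintf("P%04d", seq_len(n)) else character(0)
  sm <- config$survival_model

  grid20 <- grid30 <- counts20 <- counts30 <- NULL
  if (counts) {
    grid20 <- build_bin_grid(config$genome, config$bin_size,
                             seed = derive_seed(config$seed, "grid20"))
    grid30 <- build_bin_grid(config$genome, config$bin_size_30kb,
                             seed = derive_seed(config$seed, "grid30"))
    counts20 <- matrix(0L, nrow(grid20), n,
                       dimnames = list(NULL, ids))
    counts30 <- matrix(0L, nrow(grid30), n,
                       dimnames = list(NULL, ids))
  }

  profile <- with_seed(derive_seed(config$seed, "profiles"), {
    if (n > 0) sample(PROFILES, n, replace = TRUE,
                      prob = config$profile_proportions)
    else character(0)
  })
  qc_pass <- with_seed(derive_seed(config$seed, "quality"),
                       stats::runif(n) >= config$quality_fail_rate)

  # within-BRCAm composition: germline/somatic BRCA1/2 mutation vs
  # methylation-only, at the published 25/25/18/10/27 split
  brca_types <- c("germline_BRCA1", "somatic_BRCA1", "germline_BRCA2",
                  "somatic_BRCA2", "methylation_only")
  brca_probs <- c(25, 25, 18, 10, 27) / 105

  immune <- vector("list", n)
  col <- list(age_years = numeric(n), figo_stage = character(n),
              therapy_sequence = character(n), debulking = character(n),
              brca_mutation = character(n), brca1_methylation = logical(n),
              CD8_max = rep(NA_integer_, n), CD20_max = rep(NA_integer_, n),
              CD68_max = rep(NA_integer_, n),
              CD103_max = rep(NA_integer_, n),
              os_months = numeric(n), os_event = integer(n),
              pfs_months = numeric(n), pfs_event = integer(n),
              hrd_like = logical(n), ccne1_truth = character(n),
              true_hazard = numeric(n))
  for (i in seq_len(n)) {
    id <- ids[i]
    pr <- profile[i]
    if (counts) {
      segs <- simulate_cn_segments(pr, config,
                                   derive_seed(config$seed,
                                               paste0(id, ":cn")))
      cp20 <- project_copy_states(segs, grid20)
      cp30 <- project_copy_states(segs, grid30)
      counts20[, i] <- simulate_read_counts(
        cp20, grid20, config, derive_seed(config$seed, paste0(id, ":c20")))
      counts30[, i] <- simulate_read_counts(
        cp30, grid30, config, derive_seed(config$seed, paste0(id, ":c30")))
    } else {
      # roster-only mode: only the coarse truth attributes are needed; draw
      # them directly (same child-seed scheme, own subkey)
      segs <- with_seed(derive_seed(config$seed, paste0(id, ":cnlite")), {
        hrd_like <- pr %in% HRD_LIKE_PROFILES ||
          (pr == "BRCAm" && stats::runif(1) < config$brca_hrd_fraction)
        cc <- if (pr %in% CCNE1_PROFILES) {
          if (stats::runif(1) < config$p_amplification) "amplification"
          else "gain"
        } else "none"
        structure(data.frame(), hrd_like = hrd_like, ccne1_truth = cc)
      })
    }
    imm <- simulate_immune_counts(pr, config,
                                  derive_seed(config$seed, paste0(id, ":imm")))
    immune[[i]] <- imm
    max_cd103 <- aggregate_cores(imm$counts["CD103", ], imm$has_tumor)
    cd103_high <- !is.na(max_cd103) && max_cd103 > BINARY_CUTS["CD103"]
    surv <- simulate_survival(pr, cd103_high, config,
                              derive_seed(config$seed, paste0(id, ":surv")))

    brca <- "none"; meth <- FALSE
    if (pr == "BRCAm") {
      bt <- with_seed(derive_seed(config$seed, paste0(id, ":brca")),
                      sample(brca_types, 1, prob = brca_probs))
      if (bt == "methylation_only") meth <- TRUE else brca <- bt
    }

    clin <- with_seed(derive_seed(config$seed, paste0(id, ":clin")), {
      age_cat <- draw_cat(CLINICAL_TABLES$age, pr)
      age <- switch(age_cat, "<65" = stats::runif(1, 45, 65),
                    "65-75" = stats::runif(1, 65, 75),
                    ">75" = stats::runif(1, 75, 90))
      list(age_years = round(age, 1),
           figo_stage = draw_cat(CLINICAL_TABLES$figo, pr),
           therapy_sequence = if (stats::runif(1) <
                                  CLINICAL_TABLES$therapy_pds[pr]) "PDS"
                              else "NACT_IDS",
           debulking = draw_cat(CLINICAL_TABLES$debulking, pr))
    })

    for (m in MARKERS)
      col[[paste0(m, "_max")]][i] <- aggregate_cores(imm$counts[m, ],
                                                     imm$has_tumor)
    col$age_years[i] <- clin$age_years
    col$figo_stage[i] <- clin$figo_stage
    col$therapy_sequence[i] <- clin$therapy_sequence
    col$debulking[i] <- clin$debulking
    col$brca_mutation[i] <- brca
    col$brca1_methylation[i] <- meth
    col$os_months[i] <- surv$os_months
    col$os_event[i] <- surv$os_event
    col$pfs_months[i] <- surv$pfs_months
    col$pfs_event[i] <- surv$pfs_event
    col$hrd_like[i] <- attr(segs, "hrd_like")
    col$ccne1_truth[i] <- attr(segs, "ccne1_truth")
    col$true_hazard[i] <- surv$true_hazard
  }
  roster <- data.frame(
    patient_id = ids, age_years = col$age_years,
    figo_stage = col$figo_stage, therapy_sequence = col$therapy_sequence,
    debulking = col$debulking, brca_mutation = col$brca_mutation,
    brca1_methylation = col$brca1_methylation, dna_quality_pass = qc_pass,
    CD8_max = col$CD8_max, CD20_max = col$CD20_max,
    CD68_max = col$CD68_max, CD103_max = col$CD103_max,
    os_months = col$os_months, os_event = col$os_event,
    pfs_months = col$pfs_months, pfs_event = col$pfs_event,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    patient_id = ids, true_profile = profile, hrd_like = col$hrd_like,
    ccne1_truth = col$ccne1_truth, brca_mutation = col$brca_mutation,
    brca1_methylation = col$brca1_methylation,
    true_hazard = col$true_hazard, stringsAsFactors = FALSE)
  out <- list(roster = roster, truth = truth, immune = immune,
              config = config)
  if (counts) {
    out$grid20 <- grid20; out$grid30 <- grid30
    out$counts20 <- counts20; out$counts30 <- counts30
  }
  out
}
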