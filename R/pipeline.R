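ratio_matrix_1mb <- function(counts, grid, qc_threshold = 0.6) {
  ids <- colnames(counts)
  profs <- lapply(seq_along(ids), function(i) {
    p <- make_ratio_profile(counts[, i], grid, ids[i], qc_threshold)
    aggregate_to_1mb(p)
  })
  mat <- do.call(cbind, lapply(profs, `[[`, "log2"))
  colnames(mat) <- ids
  list(matrix = mat, grid = profs[[1]]$grid,
       qc = vapply(profs, `[[`, TRUE, "qc_pass"),
       mapd20 = vapply(profs, `[[`, 0, "noise_mapd"))
}

#' Train the BRCA-like NSC classifier on a labeled synthetic cohort
#'
#' Simulates a labeled training cohort, builds calibrated 1 MB profiles and
#' trains the shrunken-centroids model, choosing the shrinkage by
#' cross-validation. The training 1 MB average profile is kept so new
#' datasets can be calibrated onto the training scale.
#'
#' @param config a [sim_config()] (its seed is re-derived for training)
#' @param n_train training cohort size (default 200)
#' @param delta shrinkage; `NULL` (default) selects by [choose_delta()]
#' @return list with `model`, `train_matrix` (1 MB bins x samples), `grid`
#' @export
train_hrd_classifier <- function(config = sim_config(), n_train = 200,
                                 delta = NULL) {
  tr_cfg <- config
  tr_cfg$n_patients <- as.integer(n_train)
  tr_cfg$seed <- derive_seed(config$seed, "training")
  tr_cfg <- validate_sim_config(tr_cfg)
  sim <- simulate_cohort(tr_cfg, counts = TRUE)
  r1 <- ratio_matrix_1mb(sim$counts20, sim$grid20)
  y <- ifelse(sim$truth$hrd_like, "BRCA_like", "non_BRCA_like")
  X <- t(r1$matrix)
  if (is.null(delta))
    delta <- as.numeric(choose_delta(X, y, folds = 5,
                                     delta_grid = seq(0, 2, 0.25),
                                     seed = derive_seed(tr_cfg$seed, "cv")))
  model <- train_nsc(X, y, delta = delta)
  list(model = model, train_matrix = r1$matrix, grid = r1$grid)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate a cohort, build corrected 20 kb log2 ratio profiles aggregated
#' to 1 MB, calibrate them onto the classifier training scale, classify
#' BRCA-likeness, run the 30 kb segmentation/calling arm for CCNE1 status,
#' assign the stepwise molecular profiles, score immune densities, and run
#' the survival analyses (Kaplan-Meier + logrank by profile, crude and
#' covariate-adjusted Cox models for profile and density strata).
#'
#' @param config a [sim_config()]
#' @param classifier optional result of [train_hrd_classifier()] (built on
#'   the fly when `NULL`)
#' @param n_perm CBS permutations (default 1000)
#' @param verbose log stage progress
#' @return a report list; see the pipeline vignette
#' @export
run_pipeline <- function(config = sim_config(), classifier = NULL,
                         n_perm = 1000, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulate: n=%d seed=%d", config$n_patients, config$seed)
  sim <- simulate_cohort(config, counts = TRUE)
  roster <- sim$roster

  say("profile: 20 kb ratio profiles -> 1 MB")
  r1 <- ratio_matrix_1mb(sim$counts20, sim$grid20)

  if (is.null(classifier)) {
    say("classify-hrd: training NSC model")
    classifier <- train_hrd_classifier(config)
  }
  calib <- fit_calibration(classifier$train_matrix, r1$matrix)
  say("classify-hrd: calibration alpha=%.4f beta=%.4f", calib$alpha,
      calib$beta)
  Xc <- t(apply_calibration(r1$matrix, calib))
  hrd <- classify_hrd(classifier$model, Xc)
  hrd$qc_pass <- hrd$qc_pass & r1$qc
  hrd$label[!hrd$qc_pass] <- NA

  say("segment/call-ccne1: 30 kb CBS arm")
  ids <- colnames(sim$counts30)
  seg_list <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    prof <- preprocess_30kb(sim$counts30[, i], sim$grid30, ids[i])
    prof <- smooth_if_noisy(prof)
    seg_list[[i]] <- segment_cbs(prof, n_perm = n_perm,
                                 seed = derive_seed(config$seed,
                                                    paste0(ids[i], ":cbs")))
  }
  seg_list <- call_states(seg_list)
  ccne1 <- vapply(seg_list, function(s)
    ccne1_status(s, config$ccne1_locus)$status, "")

  say("assign: stepwise molecular profiles")
  roster$hrd_call <- ifelse(is.na(hrd$label), "not_tested", hrd$label)
  roster$ccne1 <- ccne1
  parts <- exclude_for_quality(roster)
  kept <- parts$kept
  kept$profile <- assign_profile(kept$brca_mutation, kept$brca1_methylation,
                                 kept$hrd_call, kept$ccne1,
                                 kept$dna_quality_pass)

  say("tme: density categories and association tests")
  tme <- tme_summary(kept)

  say("survive: KM / logrank / Cox")
  surv <- survival_report(kept)

  list(config = config, roster = kept, excluded = parts$excluded,
       truth = sim$truth, hrd_calls = hrd, segments = seg_list,
       calibration = calib,
       profile_counts = profile_summary(kept$profile), tme = tme,
       survival = surv)
}

prepare_covariates <- function(roster) {
  roster$age_group <- cut(roster$age_years, c(-Inf, 65, 75, Inf),
                          labels = c("<65", "65-75", ">75"), right = FALSE)
  roster$profile <- factor(roster$profile, levels = PROFILES)
  for (m in MARKERS)
    roster[[paste0(m, "_high")]] <-
      factor(ifelse(binary_high(roster[[paste0(m, "_max")]], m),
                    "high", "low"), levels = c("low", "high"))
  roster
}

ADJUST_SET <- c("age_group", "figo_stage", "therapy_sequence", "debulking")

#' Survival analyses mirroring the published table layout
#'
#' Kaplan-Meier medians and logrank by molecular profile, crude and
#' adjusted (age group, FIGO stage, therapy sequence, debulking) Cox models
#' for profile (BRCAm reference) and for each marker's binary density
#' stratum (low reference), for both OS and PFS.
#'
#' @param roster assigned roster (needs `profile`, density `_max` columns,
#'   survival columns, clinical covariates)
#' @return nested list by outcome
#' @export
survival_report <- function(roster) {
  roster <- prepare_covariates(roster)
  refs <- c(list(profile = "BRCAm"),
            stats::setNames(as.list(rep("low", length(MARKERS))),
                            paste0(MARKERS, "_high")))
  one_outcome <- function(time, event) {
    km <- lapply(split(roster, roster$profile), function(d)
      km_estimate(d[[time]], d[[event]]))
    lr <- logrank(roster[[time]], roster[[event]], roster$profile)
    crude <- cox_fit(roster, time, event, "profile", refs)
    adj <- cox_fit(roster, time, event, c("profile", ADJUST_SET), refs)
    dens <- lapply(stats::setNames(MARKERS, MARKERS), function(m) {
      v <- paste0(m, "_high")
      d <- roster[!is.na(roster[[v]]), ]
      list(km = lapply(split(d, d[[v]]), function(g)
             km_estimate(g[[time]], g[[event]])),
           logrank = logrank(d[[time]], d[[event]], d[[v]]),
           crude = cox_fit(d, time, event, v, refs),
           adjusted = cox_fit(d, time, event, c(v, ADJUST_SET), refs))
    })
    list(km_by_profile = km, logrank = lr, crude = crude, adjusted = adj,
         density = dens)
  }
  list(os = one_outcome("os_months", "os_event"),
       pfs = one_outcome("pfs_months", "pfs_event"))
}
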