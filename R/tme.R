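#' Aggregate per-core immune counts to the per-tumor score
#'
#' The per-tumor score of a marker is the highest count over the cores that
#' contain tumor tissue; cores without tumor tissue are excluded. If no core
#' contains tumor the score is missing.
#'
#' @param core_counts nonnegative integer counts, one per core
#' @param core_has_tumor logical per core (default all `TRUE`)
#' @return the maximum count over tumor-bearing cores, or `NA`
#' @export
aggregate_cores <- function(core_counts,
                            core_has_tumor = rep(TRUE, length(core_counts))) {
  if (!length(core_counts)) stopf("no cores")
  stopifnot(length(core_has_tumor) == length(core_counts))
  keep <- core_has_tumor & !is.na(core_counts)
  if (!any(keep)) return(NA_integer_)
  as.integer(max(core_counts[keep]))
}

ORDINAL_LEVELS <- c("0", "1-5", "6-19", "20-49", "50-100", ">100")

#' Ordinal scoring bin for an immune count
#'
#' Counts are scored as 0, 1-5, 6-19, 20-49, 50-100, or >100 positive
#' cells; 100 falls in the 50-100 bin (the >100 bin is strict).
#'
#' @param count nonnegative integer (vectorized)
#' @return factor with the six ordered score levels
#' @export
ordinal_bin <- function(count) {
  if (any(count < 0, na.rm = TRUE)) stopf("negative count")
  cut(count, breaks = c(-0.5, 0.5, 5.5, 19.5, 49.5, 100.5, Inf),
      labels = ORDINAL_LEVELS, ordered_result = TRUE)
}

#' Three-level density category (low / medium / high)
#'
#' Default mode applies the fixed published cutpoints per marker
#' (CD8/CD103: 20 and 100; CD20: 20 and 50; CD68: 50 and 100; counts below
#' the first cutpoint are low, above the second high, the upper cutpoint
#' inclusive in medium). Quartile mode instead derives the cutpoints from
#' the 25th and 75th percentiles of the supplied cohort counts.
#'
#' @param max_count per-tumor maximum counts (vectorized)
#' @param marker one of CD8, CD20, CD68, CD103
#' @param mode `"fixed"` (default) or `"quartile"`
#' @return ordered factor low < medium < high
#' @export
tri_categorize <- function(max_count, marker, mode = c("fixed", "quartile")) {
  mode <- match.arg(mode)
  marker <- match.arg(marker, MARKERS)
  cuts <- if (mode == "fixed") TRI_CUTS[[marker]] else
    stats::quantile(max_count, c(0.25, 0.75), na.rm = TRUE, type = 7)
  out <- ifelse(is.na(max_count), NA_character_,
                ifelse(max_count < cuts[1], "low",
                       ifelse(max_count > cuts[2], "high", "medium")))
  factor(out, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Two-level density stratum used in survival analysis
#'
#' Strictly above the marker's dichotomy cutoff (CD8/CD68/CD103: 100;
#' CD20: 50) is high.
#' @inheritParams tri_categorize
#' @return logical (TRUE = high), NA propagated
#' @export
binary_high <- function(max_count, marker) {
  marker <- match.arg(marker, MARKERS)
  max_count > BINARY_CUTS[[marker]]
}

#' Pearson chi-square association test on a category x profile table
#'
#' No continuity correction; zero-margin rows/columns are dropped with a
#' warning; a warning is also emitted when any expected count is below 5.
#'
#' @param tab a contingency table or matrix of counts
#' @return list with `statistic`, `df`, `p`, `expected`
#' @export
association_test <- function(tab) {
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < 5)) warning("expected counts below 5")
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

#' Proportional-odds ordinal logistic regression of density on profile
#'
#' Fits `density ~ profile` by maximum likelihood with the BRCAm profile as
#' the reference level and reports per-profile log-odds, standard errors and
#' Wald p-values. With a two-level outcome this reduces to ordinary
#' logistic regression. Complete separation is flagged with a warning.
#'
#' @param density ordered factor (>= 2 levels after dropping unused)
#' @param profile factor of molecular profiles
#' @param reference reference profile level (default `"BRCAm"`)
#' @return data.frame with term, estimate (log-odds), se, z, p
#' @export
ordinal_logistic <- function(density, profile, reference = "BRCAm") {
  keep <- !is.na(density) & !is.na(profile)
  density <- droplevels(as.ordered(density[keep]))
  profile <- stats::relevel(factor(profile[keep]), ref = reference)
  if (nlevels(density) < 2) stopf("need >= 2 outcome levels")
  if (nlevels(density) == 2) {
    fit <- stats::glm(density ~ profile, family = stats::binomial())
    cf <- summary(fit)$coefficients
    cf <- cf[grep("^profile", rownames(cf)), , drop = FALSE]
  } else {
    fit <- suppressWarnings(MASS::polr(density ~ profile, Hess = TRUE))
    cf <- summary(fit)$coefficients
    cf <- cf[grep("^profile", rownames(cf)), , drop = FALSE]
    cf <- cbind(cf, 2 * stats::pnorm(-abs(cf[, "t value"])))
  }
  if (any(abs(cf[, 1]) > 10))
    warning("possible separation: extreme ordinal-logistic coefficients")
  data.frame(term = sub("^profile", "", rownames(cf)),
             estimate = cf[, 1], se = cf[, 2], z = cf[, 1] / cf[, 2],
             p = 2 * stats::pnorm(-abs(cf[, 1] / cf[, 2])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the density table and association tests for a scored roster
#'
#' For each marker, cross-tabulates the three-level density category against
#' the assigned molecular profile and runs the chi-square association test.
#'
#' @param roster data.frame with `<marker>_max` columns and a `profile`
#'   column
#' @param mode `"fixed"` or `"quartile"` categorization
#' @return list per marker: `table` (3 x profiles) and `test`
#' @export
tme_summary <- function(roster, mode = "fixed") {
  out <- list()
  for (m in MARKERS) {
    cat3 <- tri_categorize(roster[[paste0(m, "_max")]], m, mode)
    tab <- table(cat3, factor(roster$profile, levels = PROFILES))
    out[[m]] <- list(table = tab,
                     test = suppressWarnings(association_test(tab)))
  }
  out
}
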