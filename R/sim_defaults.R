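PROFILES <- c("BRCAm", "nonBRCAmutHRD", "CCNE1", "double", "NSMP")
MARKERS <- c("CD8", "CD20", "CD68", "CD103")

# Gamma-Poisson immune model, calibrated so that the low/medium/high
# category probabilities of the per-tumor maximum of 4 Poisson cores match
# the published per-profile category frequencies (fixed marker cutpoints).
# Patient-level core mean lambda ~ Gamma(shape, mean mu); cores iid
# Poisson(lambda).
IMMUNE_SHAPE <- structure(c(1.3273, 1.2994, 0.8184, 1.0896, 0.7197, 0.5749,
  0.9228, 0.9001, 0.5644, 0.6625, 0.4894, 0.4327, 0.9969, 0.3048, 0.5963,
  0.7264, 0.5476, 0.6622, 0.8339, 0.8158), dim = c(5L, 4L),
  dimnames = list(PROFILES, MARKERS))
IMMUNE_MEAN <- structure(c(78.61, 54.268, 55.444, 62.144, 93.527, 27.409,
  18.867, 13.282, 22.107, 27.463, 159.95, 62.393, 56.199, 70.959, 46.615,
  71.845, 53.578, 37.579, 50.673, 51.112), dim = c(5L, 4L),
  dimnames = list(PROFILES, MARKERS))

# P(per-tumor CD103 maximum > 100 | profile) under the immune model above;
# used to normalize the density hazard multiplier to mean one per profile.
CD103_P_HIGH <- c(BRCAm = 0.276, nonBRCAmutHRD = 0.194, CCNE1 = 0.111,
                  double = 0.174, NSMP = 0.177)

# Fixed marker cutpoints for the three-density categories (low/medium/high)
# and the two-density dichotomy used in survival analysis.
TRI_CUTS <- list(CD8 = c(20, 100), CD20 = c(20, 50), CD68 = c(50, 100),
                 CD103 = c(20, 100))
BINARY_CUTS <- c(CD8 = 100, CD20 = 50, CD68 = 100, CD103 = 100)

default_genome <- function() {
  data.frame(chrom = paste0("chr", 1:22),
             length = (26 - (1:22)) * 1e6,
             stringsAsFactors = FALSE)
}

# Recurrent copy-number signature regions for HRD-like genomes. A shrunken
# centroid classifier detects class differences in mean profiles, so the
# BRCA-like phenotype is modeled as a mixture of recurrent aberrations
# (fixed regions with fixed direction, each altered with probability
# rec_prob) plus genome-wide scattered segments.
default_hrd_regions <- function(genome = default_genome()) {
  chroms <- c(1, 2, 3, 4, 5, 6, 8, 10, 12, 13, 16, 18)
  dirn <- rep(c("loss", "gain"), 6)
  len <- genome$length[chroms]
  data.frame(chrom = paste0("chr", chroms),
             start = round(len / 3), end = round(len / 3) + pmin(6e6, round(len / 3)),
             direction = dirn, stringsAsFactors = FALSE)
}

#' Simulation configuration for a synthetic HGSOC cohort
#'
#' Returns the default configuration as a validated list; any field can be
#' overridden by name. The defaults describe the world the downstream
#' analyses assume: five molecular profiles at the published cohort
#' proportions, a 22-chromosome ~319 Mb toy genome with a designated CCNE1
#' locus, negative-binomial binned read counts with GC and mappability bias,
#' a gamma-Poisson immune model over four TMA cores calibrated to the
#' published density-category frequencies, and exponential survival with
#' per-profile hazards anchored to the published reference-arm median and
#' crude hazard ratios, with a CD103-density hazard multiplier.
#'
#' @param ... named overrides of any default field
#' @return an object of class `sim_config`
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_patients = 348L,
    profile_proportions = c(BRCAm = 0.302, nonBRCAmutHRD = 0.193,
                            CCNE1 = 0.129, double = 0.198, NSMP = 0.178),
    genome = default_genome(),
    bin_size = 20000L,
    bin_size_30kb = 30000L,
    mean_depth = 50,
    gc_bias_strength = 8,
    gc_optimum = 0.45,
    dispersion = 0.05,  # NB overdispersion phi: Var = mu + phi * mu^2; 0 = Poisson
    ccne1_locus = list(chrom = "chr19", start = 3e6, end = 3.4e6),
    hrd_signature = list(
      regions = default_hrd_regions(),
      rec_prob = 0.55,
      n_scatter_range = c(10L, 25L),
      scatter_len_range = c(1e6, 6e6)
    ),
    nsmp_n_range = c(0L, 2L),
    brca_hrd_fraction = 0.9,  # fraction of BRCAm genomes with HRD signature
    amp_copy_range = c(5L, 8L),
    gain_copy_range = c(3L, 4L),
    amp_len_range = c(3e5, 2e6),
    p_amplification = 17 / 45,  # vs gain, within CCNE1-positive tumors
    quality_fail_rate = 12 / 360,
    immune_model = list(shape = IMMUNE_SHAPE, mean = IMMUNE_MEAN,
                        n_cores = 4L, p_core_no_tumor = 0.05),
    survival_model = list(
      # exponential OS hazards (1/month): arm ratios are the published crude
      # hazard ratios vs the BRCAm reference; the overall level (the one
      # free parameter) is calibrated so the reference arm's Kaplan-Meier
      # median, measured as published (first crossing of 0.5, n ~ 105 with
      # uniform censoring), lands on the published 52.5 months. The 1.057
      # factor absorbs the upward skew of the first-crossing median and the
      # density-multiplier mixture.
      os_hazard = log(2) / 52.5 * 1.057 *
        c(BRCAm = 1, nonBRCAmutHRD = 1.31, CCNE1 = 2.17, double = 1.75,
          NSMP = 1.67),
      # progression hazards so total PFS hazard matches published PFS
      # medians (PFS time = min(progression, death))
      pfs_median = c(BRCAm = 22.3, nonBRCAmutHRD = 16.9, CCNE1 = 14.8,
                     double = 14.7, NSMP = 16.7),
      # conditional death-hazard ratio for CD103-high (>100) vs not,
      # calibrated so the marginal crude Cox HR matches the published 0.61;
      # normalized to mean one within each profile so profile-level hazards
      # stay anchored
      cd103_high_hr = 0.64,
      cd103_p_high = CD103_P_HIGH,
      censor_horizon = 156
    ),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown sim_config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  p <- cfg$profile_proportions
  if (length(p) != 5L || abs(sum(p) - 1) > 1e-9)
    stopf("profile_proportions must be a 5-vector summing to 1")
  cfg$genome <- as_genome(cfg$genome)
  if (any(cfg$genome$length <= 0)) stopf("chromosome lengths must be > 0")
  if (cfg$mean_depth < 0) stopf("mean_depth must be >= 0")
  loc <- cfg$ccne1_locus
  gi <- match(loc$chrom, cfg$genome$chrom)
  if (is.na(gi) || loc$start < 0 || loc$end > cfg$genome$length[gi])
    stopf("ccne1_locus outside genome")
  sm <- cfg$survival_model
  if (any(sm$os_hazard <= 0)) stopf("hazards must be > 0")
  if (sm$censor_horizon <= 0) stopf("censoring horizon must be > 0")
  structure(cfg, class = "sim_config")
}

# Per-profile clinical covariate mixes (age category, FIGO stage, therapy
# sequence, debulking outcome) matching the published cohort table; rows are
# renormalized at draw time.
CLINICAL_TABLES <- list(
  age = structure(c(.657, .433, .356, .333, .339,
                    .295, .448, .311, .478, .355,
                    .048, .119, .333, .188, .307), dim = c(5L, 3L),
    dimnames = list(PROFILES, c("<65", "65-75", ">75"))),
  figo = structure(c(.067, .075, .022, .073, 0,
                     .648, .612, .689, .594, .597,
                     .276, .284, .244, .304, .387,
                     .010, .030, .044, .029, .016), dim = c(5L, 4L),
    dimnames = list(PROFILES, c("II", "III", "IV", "unknown"))),
  therapy_pds = c(BRCAm = .467, nonBRCAmutHRD = .403, CCNE1 = .422,
                  double = .464, NSMP = .210),
  debulking = structure(c(.695, .552, .467, .493, .468,
                          .210, .373, .422, .377, .387,
                          .057, .045, .111, .101, .129,
                          .038, .030, 0, .029, .016), dim = c(5L, 4L),
    dimnames = list(PROFILES, c("complete", "optimal", "suboptimal",
                                "unknown")))
)
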