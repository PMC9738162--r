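---
title: "Models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgsocmp)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the places where a
genuinely open design decision had to be made. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

# The stepwise molecular classification

Each tumor receives exactly one of five molecular profiles, in strict
precedence order:

1. any germline or somatic *BRCA1/2* mutation → **BRCAm**;
2. else *BRCA1* promoter methylation → **BRCAm**;
3. else a BRCA-like (HRD) copy-number call **and** a *CCNE1*
   gain/amplification → **double classifier**;
4. else an HRD call alone → **non-BRCAmut HRD**;
5. else a *CCNE1* gain/amplification alone → **CCNE1**;
6. else → **NSMP**.

The hierarchy encodes the biology that *BRCA* deficiency, *BRCA1*
methylation and *CCNE1* amplification are (largely) mutually exclusive
lesions, and that "BRCA-ness" is by definition a property of
*BRCA*-wild-type tumors. Downstream tests are short-circuited for
mutation carriers; `not_tested` is distinct from negative in the data
model but identical in assignment effect (`assign_profile` treats both as
absent evidence). Records failing DNA quality are excluded before
assignment (`exclude_for_quality`), never silently dropped inside it.

# Copy-number profiles from shallow WGS

**Binning and corrections (HRD arm, 20 kb).** Reads with mapping quality
strictly greater than 15 are counted into half-open 20 kb bins (0-based,
BED convention). Counts are divided by a lowess-smoothed median count per
GC value (span 0.3, fitted on non-blacklisted nonzero bins; the span is a
convention of shallow-WGS pipelines and is validated by a decorrelation
property test, |Spearman ρ| < 0.05 after correction), then by per-bin
mappability; bins with mappability < 0.2 become missing. Log2 ratios are
taken against the profile median and re-centered so the non-missing median
is exactly 0. Profile noise is summarized by MAPD (median absolute
difference of successive ratios within chromosomes); automated QC fails a
20 kb profile at MAPD ≥ 0.6. The 20 kb ratios are aggregated to 1 MB bins
as the mean of non-missing constituents, with a ≥ 50 % constituent rule
(both the rule and the threshold are our choice; they only matter for
heavily censored regions).

**Cross-platform calibration.** The BRCA-like classifier was conceived on
a different measurement platform, so new data are mapped onto the training
scale by an affine correction: compute the per-bin average ratio within
the training set and within the current set, sort both vectors, and
regress sorted-training on sorted-current by OLS. The intercept α corrects
centering, the slope β corrects scaling, applied as α + β·ratio. The
regression orientation (training on current) is our choice — it makes the
correction map current data onto the training scale; self-calibration is
the identity to numerical precision (tested at 1e-8).

**The shrunken-centroids (PAM) classifier.** With class centroids
$\bar x_{ik}$, overall centroid $\bar x_i$, pooled within-class SD $s_i$,
fudge $s_0 = \mathrm{median}_i(s_i)$ and $m_k = \sqrt{1/n_k - 1/n}$:

$$d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k (s_i + s_0)}, \qquad
  d'_{ik} = \mathrm{sign}(d_{ik})\max(0, |d_{ik}| - \Delta),$$

shrunken centroids $\bar x'_{ik} = \bar x_i + m_k (s_i+s_0) d'_{ik}$,
discriminant $\delta_k(x) = \sum_i (x_i - \bar x'_{ik})^2/(s_i+s_0)^2 -
2\log\pi_k$ and softmax posteriors. At $\Delta = 0$ this is diagonal LDA
(tested against a closed-form oracle). A profile is called non-BRCAmut
HRD when the BRCA-like posterior exceeds 0.5; a posterior of exactly 0.5
is non-BRCA-like (the published rule is ≤ 0.5 → non-BRCA-like). Missing
features are imputed with the overall centroid — they then contribute to
every class identically up to the shrunken offset — and a sample missing
more than half its features fails QC with no label. The original model's
shrinkage is unpublished; Δ is chosen by stratified 5-fold
cross-validation with the one-SE rule (conventional, favors sparsity).
Because the original training cohort and centroids are unavailable, the
package trains its own NSC on labeled synthetic profiles; the acceptance
surface is label recovery (sensitivity and specificity ≥ 0.9 end-to-end),
not reproduction of the original weights.

**Segmentation and calling (CCNE1 arm, 30 kb).** Counts are binned at
30 kb, blacklisted bins removed, GC/mappability corrected, log2
normalized, and outliers removed (|ratio − running median₅| > 4 × MAPD).
Noisy profiles (MAPD > 0.45) are smoothed by a centered rolling median
(window 9) — the gate guarantees high-quality profiles pass through
bit-identically, preserving unbiased segmentation; a rolling median moves
a clean step edge by at most half a window (tested). Circular binary
segmentation maximizes the two-sample t statistic between every circular
arc and its complement (exhaustive scan, compiled; proven equal to a
brute-force R search at n ≤ 100), accepting a split when its permutation
p-value is below α = 0.01 (1000 permutations, seeded). Two standard
curtailments keep cohort-scale runs inside the time budget without
changing decisions in practice: permutations stop as soon as the
exceedance count precludes significance, and a split is accepted at the
100-permutation checkpoint when no exceedance occurred (p = 1/101 < α);
additionally the permutation stage is skipped entirely when the observed
statistic is at the null level (2 log #arcs — p set to 0.5) or so far
above it that a union bound puts every permutation p at its floor
(< 1e-6). Adjacent segments with means closer than 0.1 log2 are merged;
minimum segment width is 2 bins.

Discrete states come from a 4-component 1-D Gaussian mixture over
bin-weighted segment means (loss < neutral < gain < amplification, the
neutral mean clamped to ±0.1), fitted by EM from fixed initial means
(−1, 0, 0.585, 1.32 — the log2 ratios of copies 1, 2, 3, 5 at full
purity), pooling segments across samples for stability. Whenever a
component empties, the ordering breaks, or EM fails to converge within
500 iterations, fixed thresholds take over: loss < −0.25, neutral
[−0.25, 0.25], gain (0.25, 0.85], amplification > 0.85 (≈ copy 3 and
copy ≥ 5 at full purity; the original cutoffs are unpublished). *CCNE1*
status is the strongest call among segments overlapping the locus
(half-open overlap; amplification ≻ gain ≻ none). The analysis arm pools
gain and amplification into one CCNE1-positive group, as the cohort
tables do, while preserving the sub-labels.

# Immune-density scoring

Four 1-mm TMA cores per tumor are counted for CD8, CD20, CD68 and CD103;
cores without tumor tissue are excluded and the per-tumor score is the
**highest** remaining core. Scores are binned ordinally (0, 1–5, 6–19,
20–49, 50–100, >100; 100 belongs to 50–100) and categorized as
low/medium/high at fixed marker cutpoints (CD8/CD103: 20 and 100; CD20:
20 and 50; CD68: 50 and 100) with the upper cutpoint inclusive in medium.
The source describes the categories both as quartile-based and by these
printed cutpoints without reconciling the two; the package defaults to
the fixed cutpoints (reproducible without raw data) and offers a
quartile mode. Survival analyses dichotomize at >100 (CD8/CD68/CD103) or
>50 (CD20), strictly. Profile–density association uses Pearson
chi-square without continuity correction (zero-margin rows/columns
dropped with a warning; expected counts < 5 warned); the
profile-on-density effect uses a proportional-odds ordinal logistic model
(BRCAm reference), which provably reduces to ordinary logistic regression
for a two-level outcome.

# Survival analysis

OS is time from treatment start to death; PFS to progression or death;
patients without an event are right-censored at last follow-up. The
Kaplan–Meier estimator uses the first-crossing conventions: the median is
the earliest time with $\hat S \le 0.5$ (undefined if never reached), and
quartile times analogously. The logrank test is the standard
observed-minus-expected chi-square with hypergeometric variance; on
tie-free two-group data it equals the Cox score test (tested at 1e-6).
Cox models use Efron tie handling — the synthetic times are reported at
0.1-month resolution, so ties occur — with categorical covariates
expanded against stated references (profile: BRCAm; density: low). Age
enters as three categories (<65, 65–75, >75) matching the cohort table,
not continuously. Multivariable models screen candidates univariably at
p < 0.10, always retain the adjustment set (age group, FIGO stage,
therapy sequence, debulking outcome), and eliminate backward at a 0.05
stay threshold (the stay threshold is our choice; only the 0.10 entry
screen is published). PFS events are modeled as progression **or any
death** — the published definition uses death of disease, which the
synthetic world does not distinguish; this divergence is deliberate and
documented.

# The synthetic cohort generator: a stated world

The generator exists so that every downstream stage is testable without
any data access. Its defaults *are* the cohort it emulates; none of them
is a tuning knob.

**Genome.** A 22-chromosome toy genome of 319 Mb (chromosome *i* has
(26 − *i*) Mb) with a designated CCNE1 locus at chr19:3.0–3.4 Mb. The
source mixes two reference builds between its two sequencing arms, so the
pipeline is deliberately build-agnostic and a desk-scale genome loses
nothing tested here. Bins carry Beta(21, 29) GC (mean 0.42),
Beta(18, 1.5) mappability and a 1 % blacklist.

**Copy-number phenotypes.** Background copy 2. NSMP and the ~10 % of
BRCAm genomes without the HRD phenotype carry 0–2 scattered alterations.
HRD-like genomes (non-BRCAmut HRD, double, 90 % of BRCAm) combine
**recurrent signature regions** — 12 fixed regions with fixed
loss/gain direction, each altered with probability 0.55 — with 10–25
scattered copy 1/3 segments of 1–6 Mb. The recurrent component is a
deliberate design decision: a shrunken-centroids classifier detects
differences in class *mean* profiles, and purely random alteration
placement produces nearly identical class means regardless of how
different individual genomes look; real BRCA-like classifiers likewise
key on recurrent aberrations. CCNE1-positive genomes add one focal
amplicon (0.3–2 Mb) overlapping the locus, copy 5–8 with probability
17/45 (amplification) or copy 3–4 otherwise (gain), matching the
published amplification:gain ratio. The locus ± 500 kb is reserved in all
other genomes so truth labels stay mutually exclusive. Note copy 4 at
full purity (log2 = 1.0) exceeds the 0.85 amplification threshold, so
some gain-truth tumors are sub-labeled amplification; the pooled
CCNE1-positive group, which is what the analysis uses, is unaffected.

**Read counts.** Negative binomial with mean
`mean_depth × mappability × (copy/2) × exp(−strength (GC − 0.45)²)` and
overdispersion φ (Var = μ + φμ²; φ → 0 recovers Poisson). Defaults:
50 reads/bin at copy-neutral (shallow-WGS scale for 20–30 kb bins),
GC-bias strength 8, φ = 0.05. These produce 30 kb MAPDs around 0.35 —
noisy enough to exercise the corrections and occasionally the smoothing
gate, clean enough to pass QC.

**Immune counts.** Per profile and marker, a patient draws a core-level
mean λ from a gamma distribution and four cores are Poisson(λ). A pure
Poisson cannot reproduce the published category tables (max of four
Poisson cores cannot put mass both below 20 and above 100), so the
gamma layer carries the between-patient spread; the (shape, mean) pairs
were fitted once, by numerical integration, so that the implied
low/medium/high probabilities of the per-tumor maximum match the
published per-profile category fractions (residual SSE < 1e-13 per
cell; the fit script is not part of the package). The fitted means
preserve the published ordering — BRCAm highest, CCNE1 lowest, for every
marker. A core lacks tumor tissue with probability 0.05 (at least one
tumor core is guaranteed).

**Survival.** Latent death times are exponential. The five arm hazards
are the published crude hazard ratios (1 / 1.31 / 2.17 / 1.75 / 1.67
versus BRCAm) times a single level parameter; the level is the one
quantity the published tables do not print directly, and it is solved so
that the reference arm's *measured* KM median (mean over simulated
n = 348 cohorts, first-crossing convention) lands on the published 52.5
months — giving log(2)/52.5 × 1.057, the 5.7 % absorbing the upward skew
of the first-crossing median under censoring and the density-multiplier
mixture. The published per-arm medians and hazard ratios are not jointly
consistent with proportional exponential hazards (52.5/28.0 = 1.875 ≠
2.17), so a choice was forced: the generator follows the hazard ratios
and anchors only the reference median. CD103-high patients (per-tumor
maximum > 100) have their death hazard multiplied by a conditional ratio
of 0.64, normalized to mean one within each profile so arm-level hazards
stay anchored; 0.64 was solved (once, by simulation) so that the
*marginal* crude CD103 hazard ratio — attenuated by profile confounding,
since BRCAm tumors are both immune-rich and long-lived — matches the
published 0.61. Only CD103 carries a causal multiplier: the other
markers' published crude effects arise in this world through their
correlation with profile, and adding three more confounded multipliers
would make the calibration non-identifiable. Progression hazards are set
so each arm's total PFS hazard matches the published PFS medians
(PFS = min(progression, death), guaranteeing PFS ≤ OS patient-wise).
Censoring is administrative, uniform on (0, 156) months — 156 months is
the maximum follow-up implied by the accrual window and the registry
cutoff. Times are reported at 0.1-month resolution (floor 0.1), which
produces the ties that motivate Efron handling.

**Reproducibility.** Every per-patient quantity uses a child seed derived
from the master seed and the patient id via a rolling-byte hash
(`derive_seed`), so subsetting or reordering a cohort never changes an
individual's draw, and a fixed seed gives bit-identical output (tested).

**What a green test does and does not establish.** The generator
reproduces the *statistical structure* the analyses assume — proportions,
copy-number phenotypes at shallow-WGS noise levels, category frequencies,
survival ratios. It does not emulate tumor purity or subclonality,
platform batch effects, read-level artifacts, inter-marker correlation
beyond the shared profile, informative censoring, or pathology review.
A green suite therefore certifies the pipeline's internal correctness and
its recovery of known truths at realistic noise — not clinical validity
on real cohorts.

# Numerical choices, degenerate inputs, tie-breaks

* MAPQ "over 15" is strict (>); coordinates are 0-based half-open
  everywhere internally, BED dialect on disk.
* GC correction requires ≥ 100 usable bins; an all-zero profile is an
  error, as is a zero median at log2 time.
* Calibration errors out on a constant sorted vector ("underdetermined")
  and on fewer than two samples per set; β ≤ 0 is rejected.
* NSC: singleton classes and negative Δ are errors; posterior ties at
  exactly 0.5 go to non-BRCA-like; `choose_delta` breaks one-SE ties
  upward (sparser model).
* CBS: chromosomes shorter than 2 × min-width return a single segment
  without error; permutation seeds derive from the master seed and the
  chromosome name, so chromosome order is irrelevant (tested).
* Mixture calling needs ≥ 5 segments, otherwise thresholds; EM
  non-convergence warns and falls back.
* KM on a group with no events flags the median as undefined rather than
  guessing; logrank drops empty groups with a warning; Cox flags
  separation (|coef| > 15) with a warning instead of failing.
* `simulate_cohort(n = 0)` returns empty frames without error.

# Known limitations

* The NSC model is trained on synthetic labels; its weights have no
  claim to equivalence with the original array-trained classifier.
* The mixture caller is a 4-state model without cellularity correction;
  copy-4 gains at full purity sit above the amplification threshold (see
  above).
* Multi-sample joint segmentation, BAF/purity/ploidy modeling, and
  competing-risks or time-varying survival models are out of scope.
* The run-scale CBS uses curtailed permutation tests; exact-permutation
  behavior is guaranteed only in the borderline band where curtailment
  never triggers (and the arc search itself is oracle-exact).
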