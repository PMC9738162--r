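# Shared fixtures, built in code. The small genome keeps count-level tests
# fast; cohort-scale tests use the default configuration and say so when
# they scale the cohort size down.

small_genome <- function() {
  data.frame(chrom = c("chr1", "chr2", "chr19"),
             length = c(12e6, 8e6, 7e6), stringsAsFactors = FALSE)
}

small_config <- function(...) {
  sim_config(genome = small_genome(),
             hrd_signature = list(
               regions = data.frame(chrom = c("chr1", "chr2"),
                                    start = c(2e6, 1e6), end = c(5e6, 3e6),
                                    direction = c("loss", "gain"),
                                    stringsAsFactors = FALSE),
               rec_prob = 0.55, n_scatter_range = c(3L, 8L),
               scatter_len_range = c(5e5, 2e6)),
             ...)
}

# memoized default-config cohort with counts, shared across tests in a file
.fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

flat_grid <- function(n_bins = 400, bin_size = 1000L, chroms = 1L,
                      seed = 7L) {
  # grid with benign annotation: mappability 1, no blacklist, mid GC
  per <- n_bins / chroms
  g <- build_bin_grid(
    data.frame(chrom = paste0("chr", seq_len(chroms)),
               length = per * bin_size),
    bin_size = bin_size, blacklist_frac = 0, seed = seed)
  g$mappability <- 1
  g$gc <- 0.45
  g
}

profile_from_ratios <- function(ratios, grid, sample_id = "s",
                                noise = mapd(ratios, grid$chrom)) {
  structure(list(sample_id = sample_id, grid = grid, log2 = ratios,
                 noise_mapd = noise, qc_pass = TRUE),
            class = "ratio_profile")
}
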