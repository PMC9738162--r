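#' Build a fixed-width bin grid over a genome
#'
#' Partitions each chromosome into half-open `[start, start + bin_size)`
#' bins (0-based, BED convention); the last bin of a chromosome is truncated
#' at the chromosome end. Each bin carries a GC fraction, a mappability in
#' `[0, 1]`, and a blacklist flag; on synthetic genomes these are drawn from
#' the distributions below, mirroring the annotation a real shallow-WGS
#' pipeline would attach to its bins.
#'
#' @param genome data.frame with columns `chrom` and `length` (bp), or a
#'   named numeric vector of chromosome lengths
#' @param bin_size bin width in bp (> 0)
#' @param gc_shape1,gc_shape2 Beta parameters for per-bin GC fraction
#' @param blacklist_frac expected fraction of blacklisted bins
#' @param seed integer seed for the annotation draws
#' @return a `bin_grid`: data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, `mappability`, `blacklist`
#' @export
build_bin_grid <- function(genome, bin_size = 20000L,
                           gc_shape1 = 21, gc_shape2 = 29,
                           blacklist_frac = 0.01, seed = 1L) {
  genome <- as_genome(genome)
  if (nrow(genome) == 0L) stopf("empty genome")
  if (bin_size <= 0) stopf("bin_size must be > 0")
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  n <- nrow(grid)
  with_seed(seed, {
    grid$gc <- stats::rbeta(n, gc_shape1, gc_shape2)
    grid$mappability <- stats::rbeta(n, 18, 1.5)
    grid$blacklist <- stats::runif(n) < blacklist_frac
  })
  grid$chrom <- factor(grid$chrom, levels = genome$chrom)
  class(grid) <- c("bin_grid", "data.frame")
  attr(grid, "bin_size") <- as.integer(bin_size)
  grid
}

as_genome <- function(genome) {
  if (is.numeric(genome) && !is.null(names(genome)))
    genome <- data.frame(chrom = names(genome), length = unname(genome),
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(genome), all(c("chrom", "length") %in% names(genome)))
  if (nrow(genome) && any(genome$length <= 0)) stopf("chromosome lengths must be > 0")
  genome
}

#' Locate the bins overlapping a genomic interval
#'
#' Half-open interval overlap against the half-open bins of a grid.
#'
#' @param grid a `bin_grid`
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @return integer row indices of overlapping bins
#' @export
bins_overlapping <- function(grid, chrom, start, end) {
  if (!chrom %in% levels(grid$chrom)) stopf("chromosome %s not in grid", chrom)
  which(grid$chrom == chrom & grid$start < end & grid$end > start)
}

#' Write / read a bin grid as BED-like TSV
#'
#' Columns: chrom, start, end, gc, mappability, blacklist (0-based,
#' half-open).
#' @param grid a `bin_grid`
#' @param path file path
#' @return `read_bin_grid` returns a `bin_grid`
#' @export
write_bin_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_grid
#' @export
read_bin_grid <- function(path) {
  grid <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "mappability", "blacklist")
  if (!all(need %in% names(grid))) stopf("malformed bin grid file: %s", path)
  grid$chrom <- factor(grid$chrom, levels = unique(grid$chrom))
  class(grid) <- c("bin_grid", "data.frame")
  attr(grid, "bin_size") <- as.integer(max(grid$end - grid$start))
  grid
}
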