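#' @useDynLib hgsocmp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Child seeds make per-patient simulation reproducible under subsetting: the
#' randomness used for one patient depends only on the master seed and the
#' patient identifier, not on how many other patients are simulated.
#' The hash is a small polynomial rolling hash of the UTF-8 bytes of `key`,
#' folded into the positive 32-bit integer range.
#'
#' @param seed master integer seed
#' @param key character scalar (e.g. a patient id)
#' @return an integer in [0, 2^31 - 1]
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Median absolute pairwise difference of successive values
#'
#' Noise metric for log2 ratio profiles: the median of |r[b+1] - r[b]| over
#' successive non-missing bins, computed within chromosomes so that
#' chromosome boundaries do not contribute spurious jumps.
#'
#' @param x numeric vector of log2 ratios (may contain NA)
#' @param chrom optional chromosome factor aligned to `x`
#' @return the MAPD (NA if fewer than 2 usable bins)
#' @export
mapd <- function(x, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep(1L, length(x))
  d <- unlist(lapply(split(x, chrom), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(numeric(0))
    abs(diff(v))
  }), use.names = FALSE)
  if (!length(d)) return(NA_real_)
  stats::median(d)
}
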