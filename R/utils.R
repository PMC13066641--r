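#' @useDynLib accessoryscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rpois runif anova lm pf median sd setNames
#' @importFrom utils read.delim write.table
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Percentage of a count over a denominator
#'
#' Convenience used throughout reporting tables: `100 * n / total`, rounded
#' to a fixed number of decimals (one by default, matching the reporting
#' style used for shared-gene and TE-embedding proportions).
#'
#' @param n Numerator count.
#' @param total Denominator count; must be positive.
#' @param digits Decimals to keep.
#' @return Numeric percentage.
#' @examples
#' pct_of(332, 2340) # 14.2
#' @export
pct_of <- function(n, total, digits = 1) {
  if (any(total <= 0)) stop("`total` must be positive")
  round(100 * n / total, digits)
}

#' Length of a 1-based, end-exclusive interval
#'
#' All anchor, block and structural-variant coordinates in this package are
#' 1-based with an exclusive end, so a printed span's length is simply
#' `end - start`.
#'
#' @param start,end Interval bounds.
#' @return `end - start`.
#' @examples
#' interval_span(2260933, 2275108) # 14175
#' @export
interval_span <- function(start, end) {
  if (any(end < start)) stop("`end` must be >= `start`")
  end - start
}

random_dna <- function(n) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, n, replace = TRUE)])
}

random_protein <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
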