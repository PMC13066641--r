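#' Load a 1-kb window depth track
#'
#' Reads (or validates) a depth track with columns `chrom`, `window_start`
#' (0-based) and `depth`, checking window sizing, ordering and value
#' sanity. Violations are reported with the offending line number.
#'
#' @param x Path to a tab-separated file with a header, or an equivalent
#'   data frame.
#' @param window Expected window size (bp).
#' @return Object of class `depth_profile`: list with `windows` (validated,
#'   ordered data frame) and `window`.
#' @export
load_windows <- function(x, window = 1000L) {
  d <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else x
  req <- c("chrom", "window_start", "depth")
  if (!all(req %in% names(d))) {
    stop("depth track must have columns chrom, window_start, depth")
  }
  line <- seq_len(nrow(d)) + 1L # header is line 1 in the file
  bad <- which(!is.finite(d$depth) | d$depth < 0)
  if (length(bad) > 0) {
    stop(sprintf("negative or non-numeric depth at line %d", line[bad[1]]))
  }
  bad <- which(d$window_start %% window != 0 | d$window_start < 0)
  if (length(bad) > 0) {
    stop(sprintf("window start not a multiple of %d at line %d", window,
                 line[bad[1]]))
  }
  key <- paste(d$chrom, d$window_start)
  bad <- which(duplicated(key))
  if (length(bad) > 0) {
    stop(sprintf("duplicate (chrom, window_start) at line %d", line[bad[1]]))
  }
  d <- d[order(d$chrom, d$window_start), , drop = FALSE]
  rownames(d) <- NULL
  structure(list(windows = d, window = as.integer(window)),
            class = "depth_profile")
}

#' Normalized chromosome copy number from window depths
#'
#' Each chromosome's mean window depth is divided by a baseline: either the
#' median of core-chromosome mean depths (`"core_median"`, the default --
#' robust when large aneuploid accessory chromosomes shift the genome mean)
#' or the genome-wide mean depth (`"genome_mean"`). Copy numbers are
#' reported raw and rounded to two decimals, together with the per-window
#' coefficient of variation.
#'
#' @param profile A `depth_profile` (or bare data frame accepted by
#'   [load_windows()]).
#' @param core_chroms Chromosomes defining the baseline in `"core_median"`
#'   mode.
#' @param baseline `"core_median"` or `"genome_mean"`.
#' @return Data frame: `chrom`, `mean_depth`, `cn_raw`, `cn` (2 dp), `cv`.
#' @export
chromosome_copy_number <- function(profile, core_chroms = NULL,
                                   baseline = c("core_median", "genome_mean")) {
  baseline <- match.arg(baseline)
  if (!inherits(profile, "depth_profile")) profile <- load_windows(profile)
  d <- profile$windows
  means <- tapply(d$depth, d$chrom, mean)
  cvs <- tapply(d$depth, d$chrom, function(v) {
    if (mean(v) == 0) NA_real_ else sd(v) / mean(v)
  })
  base <- if (baseline == "genome_mean") {
    mean(d$depth)
  } else {
    if (is.null(core_chroms)) {
      stop("`core_chroms` is required for the core_median baseline")
    }
    core_chroms <- intersect(core_chroms, names(means))
    if (length(core_chroms) == 0) stop("no core chromosomes in profile")
    median(means[core_chroms])
  }
  if (base <= 0) stop("baseline depth is zero; cannot normalize")
  data.frame(chrom = names(means), mean_depth = unname(means),
             cn_raw = unname(means / base),
             cn = round(unname(means / base), 2),
             cv = unname(cvs), stringsAsFactors = FALSE)
}

#' Call copy-number events from normalized copy numbers
#'
#' `absent` below 0.05x, `loss` below `1 - tolerance`, `gain` above
#' `1 + tolerance`, otherwise `normal`.
#'
#' @param cn Numeric vector of normalized copy numbers (or the data frame
#'   from [chromosome_copy_number()]).
#' @param tolerance Deviation from 1.0 tolerated as normal (default 0.25).
#' @param absent_below Copy number below which a chromosome is called
#'   absent.
#' @return Character vector of events (or the input data frame with an
#'   `event` column).
#' @export
call_cnv_events <- function(cn, tolerance = 0.25, absent_below = 0.05) {
  if (is.data.frame(cn)) {
    cn$event <- call_cnv_events(cn$cn_raw, tolerance, absent_below)
    return(cn)
  }
  ifelse(cn < absent_below, "absent",
         ifelse(cn < 1 - tolerance, "loss",
                ifelse(cn > 1 + tolerance, "gain", "normal")))
}
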