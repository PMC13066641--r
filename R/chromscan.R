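#' Scan chromosome ends for telomeric repeat arrays
#'
#' Looks for tandem runs of the 5' telomere motif (default `TAACCCCC`)
#' within the first `window` bp and of the 3' motif (default `TTAGGGGG`)
#' within the last `window` bp. A run counts when at least `min_copies`
#' consecutive motif-length units each match with at most `max_mismatch`
#' substitutions.
#'
#' @param seq Chromosome sequence (non-empty DNA string).
#' @param window Search window at each end (bp).
#' @param min_copies Minimum tandem copies required to call a telomere.
#' @param max_mismatch Mismatches tolerated per motif copy.
#' @param motif5,motif3 Telomere repeat units for the 5' and 3' ends.
#' @return List with `telo5` and `telo3`, each `list(present, copies)`
#'   where `copies` is the longest tandem run found in the window.
#' @examples
#' scan_telomeres(paste0(strrep("TAACCCCC", 5), strrep("A", 2000)))
#' @export
scan_telomeres <- function(seq, window = 500L, min_copies = 3L,
                           max_mismatch = 1L,
                           motif5 = "TAACCCCC", motif3 = "TTAGGGGG") {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    stop("`seq` must be a non-empty sequence")
  }
  if (window < min_copies * nchar(motif5)) {
    stop("`window` must be at least min_copies * motif length")
  }
  n <- nchar(seq)
  w <- min(window, n)
  head_seq <- substr(seq, 1, w)
  tail_seq <- substr(seq, n - w + 1, n)
  c5 <- max_tandem_run(head_seq, motif5, max_mismatch)
  c3 <- max_tandem_run(tail_seq, motif3, max_mismatch)
  list(telo5 = list(present = c5 >= min_copies, copies = c5),
       telo3 = list(present = c3 >= min_copies, copies = c3))
}

# Longest run of consecutive motif-length units (step = motif length), each
# within `max_mismatch` of the motif, anywhere in `s`.
max_tandem_run <- function(s, motif, max_mismatch) {
  m <- nchar(motif)
  n <- nchar(s)
  if (n < m) return(0L)
  x <- strsplit(s, "")[[1]]
  mm <- integer(n - m + 1)
  mchars <- strsplit(motif, "")[[1]]
  for (j in seq_len(m)) {
    mm <- mm + (x[seq(j, j + n - m)] != mchars[j])
  }
  ok <- mm <= max_mismatch
  runs <- integer(length(ok))
  for (i in rev(seq_along(ok))) {
    runs[i] <- if (!ok[i]) 0L else 1L + if (i + m <= length(ok)) runs[i + m] else 0L
  }
  max(runs, 0L)
}

#' Classify assembly completeness from telomere flags
#'
#' Pure function of the two end flags: both present gives `"T2T"`
#' (telomere-to-telomere), one end gives `"5p_only"` / `"3p_only"`, neither
#' gives `"none"`.
#'
#' @param telo5,telo3 Logical flags (or the lists returned by
#'   [scan_telomeres()]).
#' @return One of `"T2T"`, `"5p_only"`, `"3p_only"`, `"none"`.
#' @export
classify_completeness <- function(telo5, telo3) {
  if (is.list(telo5)) telo5 <- telo5$present
  if (is.list(telo3)) telo3 <- telo3$present
  if (is.na(telo5) || is.na(telo3)) stop("telomere flags are unset")
  if (telo5 && telo3) "T2T"
  else if (telo5) "5p_only"
  else if (telo3) "3p_only"
  else "none"
}

#' rDNA tandem copy number from relative depth
#'
#' The collapsed rDNA unit attracts the reads of the whole tandem array, so
#' its copy number is the ratio of the unit's sequencing depth to the
#' single-copy baseline depth.
#'
#' @param rdna_unit_depth Mean depth over the rDNA unit interval.
#' @param single_copy_depth Mean depth over single-copy sequence (> 0).
#' @return Estimated copy number (real).
#' @examples
#' rdna_copy_number(500, 50) # 10
#' @export
rdna_copy_number <- function(rdna_unit_depth, single_copy_depth) {
  if (single_copy_depth <= 0) stop("`single_copy_depth` must be > 0")
  rdna_unit_depth / single_copy_depth
}

#' Mean window depth over an interval
#'
#' Averages 1-kb window depths whose start lies inside `[start, end)` on one
#' chromosome of a depth track; a helper for [rdna_copy_number()].
#'
#' @param depth Depth data frame (`chrom`, `window_start`, `depth`).
#' @param chrom Chromosome identifier.
#' @param start,end Interval (0-based window starts, end exclusive).
#' @return Mean depth.
#' @export
interval_mean_depth <- function(depth, chrom, start, end) {
  sel <- depth$chrom == chrom & depth$window_start >= start &
    depth$window_start < end
  if (!any(sel)) stop("no depth windows in interval")
  mean(depth$depth[sel])
}

#' Telomere completeness table for a set of chromosomes
#'
#' Runs [scan_telomeres()] and [classify_completeness()] over every sequence.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param ... Passed to [scan_telomeres()].
#' @return Data frame with `chrom`, `telo5`, `copies5`, `telo3`, `copies3`,
#'   `completeness`.
#' @export
completeness_table <- function(seqs, ...) {
  rows <- lapply(names(seqs), function(ch) {
    sc <- scan_telomeres(seqs[[ch]], ...)
    data.frame(chrom = ch,
               telo5 = sc$telo5$present, copies5 = sc$telo5$copies,
               telo3 = sc$telo3$present, copies3 = sc$telo3$copies,
               completeness = classify_completeness(sc$telo5, sc$telo3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
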