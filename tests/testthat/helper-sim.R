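# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

# Small population: 8 haplotypes, 3 core + 4 accessory groups, fast to build.
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(seed = 101, strains_per_clade = c(2L, 1L, 2L),
                      n_core_chroms = 3L, core_lengths = c(60e3, 90e3),
                      n_accessory_groups = 4L, ac_lengths = c(40e3, 60e3),
                      sv_plan = "none", ltr_plan = "none")
    .fixtures$small <- simulate_genome_set(cfg)
  }
  .fixtures$small
}

# Full default-condition population (27 haplotypes, 9 CC + 15 AC groups).
default_sim <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- simulate_genome_set(sim_config(seed = 101))
  }
  .fixtures$default
}

# Grouping result on the default population (sketch -> cluster -> classify).
default_grouping <- function() {
  if (is.null(.fixtures$grouping)) {
    gs <- default_sim()
    seqs <- flatten_sequences(gs)
    sk <- lapply(seqs, sketch_chromosome)
    cl <- cluster_homologous_chromosomes(sk)
    truth <- gs$manifest$chromosomes
    .fixtures$grouping <- classify_core_accessory(
      cl, setNames(truth$haplotype, truth$chrom),
      setNames(truth$length, truth$chrom), names(gs$sequences))
  }
  .fixtures$grouping
}

flatten_sequences <- function(gs) {
  seqs <- unlist(gs$sequences, use.names = FALSE)
  names(seqs) <- unlist(lapply(gs$sequences, names), use.names = FALSE)
  seqs
}

chrom_class_of <- function(gs) {
  with(gs$manifest$chromosomes,
       setNames(ifelse(kind == "core", "core", "accessory"), chrom))
}

# Brute-force maximal-exact-match scan over every diagonal of both strands;
# independent of the seed-and-extend implementation.
bf_mems <- function(query, target, min_len) {
  qv <- strsplit(query, "")[[1]]
  one_strand <- function(tv, strand, tlen) {
    n <- length(qv); m <- length(tv)
    out <- list()
    for (d in seq(-(m - 1), n - 1)) {
      i0 <- max(0L, d); i1 <- min(n - 1L, m - 1L + d)
      if (i1 - i0 + 1 < min_len) next
      idx <- i0:i1
      eq <- qv[idx + 1L] == tv[idx - d + 1L]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_len)) {
        qs0 <- i0 + starts[k] - 1L
        qe0 <- i0 + ends[k]
        ts0 <- qs0 - d; te0 <- qe0 - d
        if (strand == "-") {
          tmp <- c(tlen - te0, tlen - ts0)
          ts0 <- tmp[1]; te0 <- tmp[2]
        }
        out[[length(out) + 1]] <- data.frame(
          qstart = qs0 + 1L, qend = qe0 + 1L,
          tstart = ts0 + 1L, tend = te0 + 1L,
          strand = strand, length = qe0 - qs0, stringsAsFactors = FALSE)
      }
    }
    out
  }
  tv <- strsplit(target, "")[[1]]
  rc <- strsplit(accessoryscan:::revcomp(target), "")[[1]]
  out <- c(one_strand(tv, "+", length(tv)), one_strand(rc, "-", length(tv)))
  if (length(out) == 0) {
    return(data.frame(qstart = integer(0), qend = integer(0),
                      tstart = integer(0), tend = integer(0),
                      strand = character(0), length = integer(0)))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$qstart, out$tstart, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hand-computed one-way F from sums of squares.
bf_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  means <- tapply(values, groups, mean)
  ns <- table(groups)
  ssb <- sum(ns * (means - mean(values))^2)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}
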