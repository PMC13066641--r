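#' Configuration for the synthetic dikaryotic population generator
#'
#' Builds and validates the parameter set for [simulate_genome_set()]. The
#' defaults emulate a three-clade population of 16 strains (5 monokaryons and
#' 11 dikaryons, hence 27 haploid genomes) with 9 core-chromosome groups
#' shared by every haplotype and 15 clade-restricted accessory-chromosome
#' groups, at desk scale (chromosomes of a few hundred kilobases). Sequence
#' divergences, transposable-element fractions, gene densities, intron
#' counts, copy-number ratios and LTR insertion ages follow the contrasts
#' reported for core versus accessory chromosomes in *Tremella fuciformis*-
#' like populations: cross-clade core identity near 87-88%, accessory
#' homolog identity above 97%, TE fractions of 40-81% on accessory versus
#' 11-19% on core chromosomes, and accessory gene density roughly half the
#' core density with fewer introns per gene.
#'
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @param clades Number of clades.
#' @param strains_per_clade Integer vector, strains in each clade.
#' @param dikaryon_fraction Fraction of strains that are dikaryotic (two
#'   haplotypes); the per-clade dikaryon count is `round(fraction * n)`.
#' @param n_core_chroms Core chromosome groups per haplotype.
#' @param core_lengths,ac_lengths Length ranges (bp) from which ancestral
#'   core / accessory chromosome lengths are drawn.
#' @param n_accessory_groups Total accessory groups, split across clades.
#' @param core_divergence Expected pairwise mismatch proportion between core
#'   homologs of different clades.
#' @param core_divergence_within Expected pairwise mismatch proportion
#'   between core homologs within a clade.
#' @param ac_divergence Expected pairwise mismatch proportion between
#'   homologous accessory chromosomes (all carriers share a clade).
#' @param ac_loss_prob Probability that a carrier haplotype has lost a given
#'   accessory group (clade-structured presence/absence).
#' @param te_fraction_cc,te_fraction_ac Ranges for the per-chromosome
#'   repeat-covered fraction.
#' @param gene_density_cc,gene_density_ac Genes per 100 kb.
#' @param introns_per_gene_cc,introns_per_gene_ac Mean introns per gene.
#' @param shared_cc_fraction Fraction of accessory-chromosome gene families
#'   planted as diverged copies of core-chromosome genes.
#' @param te_embed_fraction Fraction of those shared genes embedded in TEs.
#' @param singleton_fraction Fraction of accessory genes planted as
#'   single-genome singletons.
#' @param telomere_copies Tandem motif copies appended to chromosome ends.
#' @param p_missing_telomere Probability that a chromosome end lacks its
#'   telomere array.
#' @param mean_depth Mean sequencing depth per 1-kb window.
#' @param rate_r Neutral substitution rate (substitutions/site/year) used to
#'   convert planted LTR ages into terminal-repeat divergence.
#' @param sv_plan `"default"`, `"none"`, or a data frame with columns
#'   `type`, `clade`, `ac_index`, `size` (one planted event per row, applied
#'   to the first carrier haplotype of that clade's `ac_index`-th group).
#' @param ltr_plan `"default"`, `"none"`, or a data frame with columns
#'   `clade`, `ac_index`, `age`, `ltr_len`, `internal_len`.
#' @param cnv_plan `"default"`, `"none"`, or a data frame with columns
#'   `clade`, `chrom_index`, `ratio` (chromosome order: cores then ACs),
#'   applied to the first dikaryon A-haplotype of the clade.
#' @param rdna_unit_len rDNA unit length (bp); the unit interval is placed on
#'   the second core chromosome of every haplotype.
#' @param rdna_copies Range of planted rDNA tandem copy numbers.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       clades = 3L,
                       strains_per_clade = c(5L, 4L, 7L),
                       dikaryon_fraction = 11 / 16,
                       n_core_chroms = 9L,
                       core_lengths = c(250e3, 450e3),
                       n_accessory_groups = 15L,
                       ac_lengths = c(120e3, 300e3),
                       core_divergence = 0.12,
                       core_divergence_within = 0.005,
                       ac_divergence = 0.005,
                       ac_loss_prob = 0.1,
                       te_fraction_cc = c(0.11, 0.19),
                       te_fraction_ac = c(0.40, 0.81),
                       gene_density_cc = 36,
                       gene_density_ac = 16,
                       introns_per_gene_cc = 3.3,
                       introns_per_gene_ac = 2.1,
                       shared_cc_fraction = 0.142,
                       te_embed_fraction = 0.771,
                       singleton_fraction = 0.042,
                       telomere_copies = 6L,
                       p_missing_telomere = 0.03,
                       mean_depth = 30,
                       rate_r = 2e-9,
                       sv_plan = "default",
                       ltr_plan = "default",
                       cnv_plan = "default",
                       rdna_unit_len = 10e3,
                       rdna_copies = c(15L, 40L)) {
  cfg <- list(
    seed = as.integer(seed), clades = as.integer(clades),
    strains_per_clade = as.integer(strains_per_clade),
    dikaryon_fraction = dikaryon_fraction,
    n_core_chroms = as.integer(n_core_chroms),
    core_lengths = core_lengths,
    n_accessory_groups = as.integer(n_accessory_groups),
    ac_lengths = ac_lengths,
    core_divergence = core_divergence,
    core_divergence_within = core_divergence_within,
    ac_divergence = ac_divergence,
    ac_loss_prob = ac_loss_prob,
    te_fraction_cc = te_fraction_cc, te_fraction_ac = te_fraction_ac,
    gene_density_cc = gene_density_cc, gene_density_ac = gene_density_ac,
    introns_per_gene_cc = introns_per_gene_cc,
    introns_per_gene_ac = introns_per_gene_ac,
    shared_cc_fraction = shared_cc_fraction,
    te_embed_fraction = te_embed_fraction,
    singleton_fraction = singleton_fraction,
    telomere_copies = as.integer(telomere_copies),
    p_missing_telomere = p_missing_telomere,
    mean_depth = mean_depth, rate_r = rate_r,
    sv_plan = sv_plan, ltr_plan = ltr_plan, cnv_plan = cnv_plan,
    rdna_unit_len = rdna_unit_len,
    rdna_copies = as.integer(rdna_copies)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field) {
    if (!ok) stop(sprintf("invalid configuration field `%s`", field), call. = FALSE)
  }
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed")
  chk(cfg$clades >= 1, "clades")
  chk(length(cfg$strains_per_clade) == cfg$clades &&
        all(cfg$strains_per_clade >= 1), "strains_per_clade")
  chk(cfg$dikaryon_fraction >= 0 && cfg$dikaryon_fraction <= 1,
      "dikaryon_fraction")
  chk(cfg$n_core_chroms >= 1, "n_core_chroms")
  chk(length(cfg$core_lengths) == 2 && all(cfg$core_lengths > 0) &&
        diff(cfg$core_lengths) >= 0, "core_lengths")
  chk(cfg$n_accessory_groups >= 0, "n_accessory_groups")
  chk(length(cfg$ac_lengths) == 2 && all(cfg$ac_lengths > 0) &&
        diff(cfg$ac_lengths) >= 0, "ac_lengths")
  for (f in c("core_divergence", "core_divergence_within", "ac_divergence")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] < 0.75, f)
  }
  for (f in c("ac_loss_prob", "shared_cc_fraction", "te_embed_fraction",
              "singleton_fraction", "p_missing_telomere")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f)
  }
  for (f in c("te_fraction_cc", "te_fraction_ac")) {
    chk(length(cfg[[f]]) == 2 && all(cfg[[f]] >= 0) && all(cfg[[f]] <= 1) &&
          diff(cfg[[f]]) >= 0, f)
  }
  chk(cfg$gene_density_cc > 0, "gene_density_cc")
  chk(cfg$gene_density_ac > 0, "gene_density_ac")
  chk(cfg$introns_per_gene_cc >= 0, "introns_per_gene_cc")
  chk(cfg$introns_per_gene_ac >= 0, "introns_per_gene_ac")
  chk(cfg$telomere_copies >= 1, "telomere_copies")
  chk(cfg$mean_depth > 0, "mean_depth")
  chk(cfg$rate_r > 0, "rate_r")
  chk(cfg$rdna_unit_len > 0, "rdna_unit_len")
  chk(length(cfg$rdna_copies) == 2 && all(cfg$rdna_copies >= 1), "rdna_copies")
  invisible(cfg)
}

# Per-branch substitution proportion q such that two sequences evolved
# independently from a common ancestor show expected pairwise mismatch p:
# p = 2q(1-q) + (2/3)q^2  =>  q = (1 - sqrt(1 - (4/3)p)) / (4/3).
branch_p_from_pairwise <- function(p) {
  a <- 4 / 3
  (1 - sqrt(1 - a * p)) / a
}

#' Apply uniform substitutions to a DNA sequence
#'
#' Substitutes a binomially sampled set of sites (each site independently
#' with probability `p`) with a uniformly chosen different base, so the
#' expected mismatch fraction against the input equals `p`. No indels are
#' introduced; sequence length is preserved.
#'
#' @param seq DNA string (A/C/G/T).
#' @param p Per-site substitution probability, in `[0, 0.75)` (the
#'   Jukes-Cantor identifiable domain).
#' @param seed Optional integer seed for a reproducible draw.
#' @return Mutated DNA string of the same length.
#' @examples
#' evolve_sequence("ACGTACGT", 0)        # unchanged
#' @export
evolve_sequence <- function(seq, p, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p >= 0.75) {
    stop("`p` must be in [0, 0.75)")
  }
  if (!is.null(seed)) return(with_seed(seed, evolve_sequence(seq, p)))
  n <- nchar(seq)
  if (p == 0 || n == 0) return(seq)
  nmut <- rbinom(1, n, p)
  if (nmut == 0) return(seq)
  pos <- sample.int(n, nmut)
  x <- charToRaw(seq)
  bases <- as.raw(c(65L, 67L, 71L, 84L)) # A C G T
  cur <- match(x[pos], bases)
  # offset 1..3 cycles to a different base
  new_idx <- ((cur - 1L + sample.int(3L, nmut, replace = TRUE)) %% 4L) + 1L
  x[pos] <- bases[new_idx]
  rawToChar(x)
}

mutate_protein <- function(seq, p) {
  n <- nchar(seq)
  nmut <- rbinom(1, n, p)
  if (nmut == 0) return(seq)
  pos <- sample.int(n, nmut)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  x <- strsplit(seq, "")[[1]]
  x[pos] <- sample(aa, nmut, replace = TRUE)
  paste(x, collapse = "")
}

#' Insert an LTR retrotransposon with age-matched terminal divergence
#'
#' Plants a full-length element (5' LTR + internal region + 3' LTR) into a
#' chromosome. Both terminal repeats start from one LTR sequence and each
#' accumulates substitutions at `r * age` per site, so their expected
#' pairwise divergence is approximately `2 * r * age` -- the quantity the
#' dating stage inverts through the Jukes-Cantor correction.
#'
#' @param seq Chromosome sequence.
#' @param ltr_len Length of each terminal repeat (bp).
#' @param internal_len Length of the internal region (bp).
#' @param age Insertion age in years (>= 0).
#' @param r Neutral substitution rate (substitutions/site/year).
#' @param insert_at 1-based position before which the element is inserted;
#'   random if `NULL`.
#' @param seed Optional seed.
#' @return List with `seq` (modified chromosome) and `truth` (insertion
#'   start, element/LTR/internal lengths, planted age).
#' @export
plant_ltr_element <- function(seq, ltr_len, internal_len, age, r = 2e-9,
                              insert_at = NULL, seed = NULL) {
  if (age < 0) stop("`age` must be >= 0")
  if (2 * r * age >= 0.75) {
    stop("expected LTR divergence 2*r*age is at or beyond Jukes-Cantor saturation (0.75)")
  }
  if (!is.null(seed)) {
    return(with_seed(seed, plant_ltr_element(seq, ltr_len, internal_len, age,
                                             r, insert_at)))
  }
  n <- nchar(seq)
  if (is.null(insert_at)) insert_at <- sample.int(n - 1L, 1) + 1L
  if (insert_at < 1 || insert_at > n + 1) stop("`insert_at` outside sequence")
  ltr <- random_dna(ltr_len)
  ltr5 <- evolve_sequence(ltr, r * age)
  ltr3 <- evolve_sequence(ltr, r * age)
  element <- paste0(ltr5, random_dna(internal_len), ltr3)
  out <- paste0(substr(seq, 1, insert_at - 1), element,
                substr(seq, insert_at, n))
  list(seq = out,
       truth = list(start = insert_at,
                    end = insert_at + nchar(element),
                    ltr_len = ltr_len, internal_len = internal_len,
                    age = age))
}

#' Simulate a per-1-kb-window read-depth track
#'
#' Draws Poisson window depths with per-chromosome means proportional to the
#' planted copy ratio: `depth ~ Poisson(mean_depth * ratio)`. A ratio of 0
#' yields all-zero windows (a lost chromosome).
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp); each
#'   chromosome gets `floor(length / window)` windows.
#' @param copy_ratios Named vector of copy ratios (>= 0), matched by name;
#'   chromosomes without an entry default to 1.
#' @param mean_depth Baseline depth per window (> 0).
#' @param seed Optional seed.
#' @param window Window size in bp (default 1000).
#' @return Data frame with columns `chrom`, `window_start` (0-based) and
#'   `depth`.
#' @export
simulate_depth_profile <- function(chrom_lengths, copy_ratios = NULL,
                                   mean_depth = 30, seed = NULL,
                                   window = 1000L) {
  if (mean_depth <= 0) stop("`mean_depth` must be > 0")
  if (any(chrom_lengths <= 0)) stop("invalid configuration field `chrom_lengths`")
  if (!is.null(copy_ratios) && any(copy_ratios < 0)) {
    stop("invalid configuration field `copy_ratios`")
  }
  if (!is.null(seed)) {
    return(with_seed(seed, simulate_depth_profile(chrom_lengths, copy_ratios,
                                                  mean_depth, NULL, window)))
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    nw <- as.integer(chrom_lengths[[ch]] %/% window)
    ratio <- if (!is.null(copy_ratios) && ch %in% names(copy_ratios)) {
      copy_ratios[[ch]]
    } else 1
    data.frame(chrom = rep(ch, nw),
               window_start = as.integer(seq_len(nw) - 1L) * as.integer(window),
               depth = if (ratio == 0) integer(nw) else rpois(nw, mean_depth * ratio),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate one homologous chromosome pair with a planted structural variant
#'
#' Generates a random chromosome, derives a homolog by uniform substitution
#' at `divergence`, and applies one structural variant to the derived copy.
#' Used for targeted recovery tests of the anchor/chain/classify stack.
#'
#' @param length Chromosome length (bp).
#' @param divergence Pairwise substitution divergence between the homologs.
#' @param sv `NULL` for a divergence-only pair, or a list with `type` in
#'   `"inversion"`, `"terminal_loss"`, `"insertion_deletion"`,
#'   `"fusion_split"` and an optional `size` (bp).
#' @param seed Optional seed.
#' @return List with `query` (single sequence), `target` (named vector of
#'   one, or two for fusion/split), and `truth` (planted event record).
#' @export
simulate_homolog_pair <- function(length = 300e3, divergence = 0.005,
                                  sv = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, simulate_homolog_pair(length, divergence, sv)))
  }
  q <- random_dna(length)
  t <- evolve_sequence(q, divergence)
  truth <- list(type = "none")
  target <- c(hom = t)
  if (!is.null(sv)) {
    type <- sv$type
    size <- as.integer(sv$size %||% switch(type,
      inversion = 80e3, terminal_loss = 40e3,
      insertion_deletion = 60e3, fusion_split = NA_integer_))
    if (type == "inversion") {
      s <- as.integer(sv$start %||% sample(seq(40e3, length - size - 40e3), 1))
      seg <- substr(t, s, s + size - 1)
      target <- c(hom = paste0(substr(t, 1, s - 1), revcomp(seg),
                               substr(t, s + size, length)))
      truth <- list(type = "inversion", start = s, end = s + size, size = size)
    } else if (type == "terminal_loss") {
      target <- c(hom = substr(t, 1, length - size))
      truth <- list(type = "terminal_loss", start = length - size + 1L,
                    end = length + 1L, size = size)
    } else if (type == "insertion_deletion") {
      s <- as.integer(sv$start %||% sample(seq(60e3, length - size - 60e3), 1))
      target <- c(hom = paste0(substr(t, 1, s - 1), substr(t, s + size, length)))
      truth <- list(type = "insertion_deletion", start = s, end = s + size,
                    size = size)
    } else if (type == "fusion_split") {
      cut <- as.integer(sv$cut %||% (length %/% 2))
      target <- c(part1 = substr(t, 1, cut), part2 = substr(t, cut + 1, length))
      truth <- list(type = "fusion_split", cut = cut)
    } else {
      stop("unknown sv type: ", type)
    }
  }
  list(query = q, target = target, truth = truth)
}

default_sv_plan <- function(clades) {
  data.frame(
    type = c("inversion", "terminal_loss", "insertion_deletion"),
    clade = (seq_len(3) - 1L) %% clades + 1L,
    ac_index = 2L,
    size = c(80e3, 40e3, 60e3),
    stringsAsFactors = FALSE
  )
}

default_ltr_plan <- function(groups_df, rate_r) {
  # two elements on the first carrier of most groups; every fifth group is
  # left without intact elements (inestimable, as in real collections)
  rows <- list()
  for (i in seq_len(nrow(groups_df))) {
    if (i %% 5 == 0) next
    ages <- round(runif(2, 2e5, 1.7e6), -4)
    rows[[length(rows) + 1]] <- data.frame(
      clade = groups_df$clade[i], ac_index = groups_df$index_in_clade[i],
      age = ages, ltr_len = 5000L, internal_len = 7000L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a complete multi-strain genome set with truth manifest
#'
#' Generates haploid genome sequences for every strain of the configured
#' population (dikaryons contribute two haplotypes, suffixed A/B), together
#' with gene models, repeat annotations, protein sequences, per-1-kb window
#' depth tracks, and a truth manifest recording every planted parameter:
#' the accessory presence/absence matrix, chromosome classes and homology
#' groups, structural variants, LTR element ages, copy ratios, rDNA copies
#' and telomere states.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `genome_set`: a list with elements
#'   `sequences` (per-haplotype named character vectors), `genes`,
#'   `repeats`, `proteins`, `depth` (data frames), `manifest`, and `config`.
#' @export
simulate_genome_set <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_genome_set_impl(config))
}

simulate_genome_set_impl <- function(cfg) {
  ## roster -----------------------------------------------------------------
  roster <- list()
  for (cl in seq_len(cfg$clades)) {
    ns <- cfg$strains_per_clade[cl]
    ndi <- round(cfg$dikaryon_fraction * ns)
    for (s in seq_len(ns)) {
      strain <- sprintf("C%dS%d", cl, s)
      di <- s <= ndi
      haps <- if (di) paste0(strain, c("A", "B")) else strain
      roster[[length(roster) + 1]] <- data.frame(
        strain = strain, clade = cl, dikaryon = di, haplotype = haps,
        stringsAsFactors = FALSE)
    }
  }
  roster <- do.call(rbind, roster)
  haps <- roster$haplotype

  ## ancestral chromosomes ---------------------------------------------------
  ncc <- cfg$n_core_chroms
  core_len <- round(sort(runif(ncc, cfg$core_lengths[1], cfg$core_lengths[2]),
                         decreasing = TRUE))
  core_anc <- vapply(core_len, random_dna, character(1))
  nac <- cfg$n_accessory_groups
  ac_groups <- data.frame(
    global = seq_len(nac),
    clade = sort(rep_len(seq_len(cfg$clades), nac)),
    stringsAsFactors = FALSE)
  ac_groups$index_in_clade <- stats::ave(ac_groups$global, ac_groups$clade,
                                         FUN = seq_along)
  ac_len <- round(runif(nac, cfg$ac_lengths[1], cfg$ac_lengths[2]))
  ac_anc <- vapply(ac_len, random_dna, character(1))

  q_between <- branch_p_from_pairwise(cfg$core_divergence)
  q_within <- branch_p_from_pairwise(cfg$core_divergence_within)
  q_ac <- branch_p_from_pairwise(cfg$ac_divergence)

  # clade-level core sequences
  clade_core <- lapply(seq_len(cfg$clades), function(cl) {
    vapply(core_anc, function(s) evolve_sequence(s, q_between), character(1),
           USE.NAMES = FALSE)
  })

  ## presence matrix ---------------------------------------------------------
  presence <- matrix(0L, nrow = nac, ncol = length(haps),
                     dimnames = list(paste0("G", seq_len(nac)), haps))
  for (g in seq_len(nac)) {
    carriers <- haps[roster$clade == ac_groups$clade[g]]
    keep <- runif(length(carriers)) >= cfg$ac_loss_prob
    if (!any(keep)) keep[1] <- TRUE
    presence[g, carriers[keep]] <- 1L
  }

  ## plans -------------------------------------------------------------------
  sv_plan <- cfg$sv_plan
  if (identical(sv_plan, "default")) sv_plan <- default_sv_plan(cfg$clades)
  if (identical(sv_plan, "none")) sv_plan <- NULL
  ltr_plan <- cfg$ltr_plan
  if (identical(ltr_plan, "default")) ltr_plan <- default_ltr_plan(ac_groups, cfg$rate_r)
  if (identical(ltr_plan, "none")) ltr_plan <- NULL
  cnv_plan <- cfg$cnv_plan
  if (identical(cnv_plan, "default")) {
    cnv_plan <- data.frame(
      clade = cfg$clades,
      chrom_index = c(min(5L, ncc), min(7L, ncc), ncc + 1L, ncc + 2L),
      ratio = c(1.5, 2.0, 0.5, 0.0),
      stringsAsFactors = FALSE)
  }
  if (identical(cnv_plan, "none")) cnv_plan <- NULL

  # first carrier haplotype of each AC group (SV / LTR planting target)
  first_carrier <- unname(apply(presence, 1, function(v) names(v)[v == 1][1]))

  ## per-haplotype assembly ---------------------------------------------------
  sequences <- list()
  chrom_rows <- list()
  sv_rows <- list()
  ltr_rows <- list()
  for (h in haps) {
    cl <- roster$clade[roster$haplotype == h]
    seqs <- character(0)
    meta <- list()
    for (k in seq_len(ncc)) {
      s <- evolve_sequence(clade_core[[cl]][k], q_within)
      seqs <- c(seqs, s)
      meta[[length(meta) + 1]] <- list(kind = "core", group = k)
    }
    for (g in which(presence[, h] == 1L)) {
      s <- evolve_sequence(ac_anc[g], q_ac)
      seqs <- c(seqs, s)
      meta[[length(meta) + 1]] <- list(kind = "ac", group = g)
    }
    names(seqs) <- sprintf("%s.chr%02d", h, seq_along(seqs))

    # plant LTR elements (on first carriers), then SVs, then telomeres
    for (i in seq_along(seqs)) {
      m <- meta[[i]]
      if (m$kind != "ac") next
      g <- m$group
      if (!identical(first_carrier[g], h)) next
      if (!is.null(ltr_plan)) {
        sel <- ltr_plan$clade == ac_groups$clade[g] &
          ltr_plan$ac_index == ac_groups$index_in_clade[g]
        for (r in which(sel)) {
          pl <- plant_ltr_element(seqs[[i]], ltr_plan$ltr_len[r],
                                  ltr_plan$internal_len[r], ltr_plan$age[r],
                                  cfg$rate_r)
          seqs[[i]] <- pl$seq
          ltr_rows[[length(ltr_rows) + 1]] <- data.frame(
            element = sprintf("LTR%03d", length(ltr_rows) + 1L),
            haplotype = h, chrom = names(seqs)[i], group = g,
            start = pl$truth$start, end = pl$truth$end,
            ltr_len = pl$truth$ltr_len, internal_len = pl$truth$internal_len,
            age = pl$truth$age, stringsAsFactors = FALSE)
        }
      }
      if (!is.null(sv_plan)) {
        sel <- sv_plan$clade == ac_groups$clade[g] &
          sv_plan$ac_index == ac_groups$index_in_clade[g]
        for (r in which(sel)) {
          n <- nchar(seqs[[i]])
          size <- as.integer(sv_plan$size[r])
          type <- sv_plan$type[r]
          if (size > n - 80e3) size <- as.integer(n %/% 3)
          if (type == "inversion") {
            s0 <- as.integer(sample(seq(30e3, n - size - 30e3), 1))
            seg <- substr(seqs[[i]], s0, s0 + size - 1)
            seqs[[i]] <- paste0(substr(seqs[[i]], 1, s0 - 1), revcomp(seg),
                                substr(seqs[[i]], s0 + size, n))
          } else if (type == "terminal_loss") {
            s0 <- n - size + 1L
            seqs[[i]] <- substr(seqs[[i]], 1, n - size)
          } else if (type == "insertion_deletion") {
            s0 <- as.integer(sample(seq(40e3, n - size - 40e3), 1))
            seqs[[i]] <- paste0(substr(seqs[[i]], 1, s0 - 1),
                                substr(seqs[[i]], s0 + size, n))
          } else stop("unsupported sv_plan type: ", type)
          sv_rows[[length(sv_rows) + 1]] <- data.frame(
            type = type, haplotype = h, chrom = names(seqs)[i], group = g,
            start = s0, end = s0 + size, size = size, stringsAsFactors = FALSE)
        }
      }
    }

    # telomeres
    telo5 <- runif(length(seqs)) >= cfg$p_missing_telomere
    telo3 <- runif(length(seqs)) >= cfg$p_missing_telomere
    t5 <- strrep("TAACCCCC", cfg$telomere_copies)
    t3 <- strrep("TTAGGGGG", cfg$telomere_copies)
    for (i in seq_along(seqs)) {
      if (telo5[i]) seqs[[i]] <- paste0(t5, seqs[[i]])
      if (telo3[i]) seqs[[i]] <- paste0(seqs[[i]], t3)
    }

    sequences[[h]] <- seqs
    chrom_rows[[length(chrom_rows) + 1]] <- data.frame(
      chrom = names(seqs), haplotype = h, clade = cl,
      strain = roster$strain[roster$haplotype == h],
      kind = vapply(meta, `[[`, character(1), "kind"),
      group_index = vapply(meta, `[[`, integer(1), "group"),
      length = nchar(seqs), telo5 = telo5, telo3 = telo3,
      stringsAsFactors = FALSE)
  }
  chroms <- do.call(rbind, chrom_rows)
  rownames(chroms) <- NULL

  ## truth group labels: CC/AC numbered by descending mean member length -----
  chroms$truth_group <- truth_group_labels(chroms)

  ## copy ratios --------------------------------------------------------------
  chroms$copy_ratio <- 1
  if (!is.null(cnv_plan)) {
    for (r in seq_len(nrow(cnv_plan))) {
      cl <- cnv_plan$clade[r]
      target_haps <- roster$haplotype[roster$clade == cl & roster$dikaryon]
      if (length(target_haps) == 0) next
      th <- target_haps[1] # first dikaryon hapA of the clade
      idx <- which(chroms$haplotype == th)
      ci <- cnv_plan$chrom_index[r]
      if (ci <= length(idx)) chroms$copy_ratio[idx[ci]] <- cnv_plan$ratio[r]
    }
  }

  ## rDNA ---------------------------------------------------------------------
  rdna_chr_index <- min(2L, ncc)
  rdna <- do.call(rbind, lapply(haps, function(h) {
    idx <- which(chroms$haplotype == h & chroms$kind == "core" &
                   chroms$group_index == rdna_chr_index)
    unit <- as.integer(cfg$rdna_unit_len)
    s <- min(100000L, as.integer(chroms$length[idx]) %/% 2L)
    s <- (s %/% 1000L) * 1000L # align to window grid
    data.frame(haplotype = h, chrom = chroms$chrom[idx],
               start = s, end = s + unit,
               copies = sample(seq(cfg$rdna_copies[1], cfg$rdna_copies[2]), 1),
               stringsAsFactors = FALSE)
  }))

  ## genes, proteins, repeats --------------------------------------------------
  ann <- simulate_annotations(cfg, chroms, roster, presence, ac_groups,
                              core_len, ac_len)
  if (length(ltr_rows)) {
    ltr_df <- do.call(rbind, ltr_rows)
    ann$repeats <- rbind(ann$repeats, data.frame(
      haplotype = ltr_df$haplotype, chrom = ltr_df$chrom,
      start = ltr_df$start, end = ltr_df$end, class = "LTR/Ty3",
      stringsAsFactors = FALSE))
    # an element can land on a gene; refresh the embedding truth for shared
    # genes from the final repeat intervals (>= 80% of span inside TE union)
    sel <- which(ann$genes$shared_cc)
    for (j in sel) {
      g <- ann$genes[j, ]
      rr <- ann$repeats[ann$repeats$chrom == g$chrom, ]
      if (nrow(rr) == 0) next
      te <- IRanges::reduce(IRanges::IRanges(rr$start, rr$end - 1L))
      ov <- IRanges::intersect(te, IRanges::IRanges(g$start, g$end - 1L))
      ann$genes$embedded[j] <- sum(IRanges::width(ov)) / (g$end - g$start) >= 0.8
    }
  }

  ## depth tracks ---------------------------------------------------------------
  depth <- do.call(rbind, lapply(haps, function(h) {
    idx <- which(chroms$haplotype == h)
    lens <- setNames(chroms$length[idx], chroms$chrom[idx])
    ratios <- setNames(chroms$copy_ratio[idx], chroms$chrom[idx])
    d <- simulate_depth_profile(lens, ratios, cfg$mean_depth)
    # rDNA unit windows collapse the tandem array: depth scales with copies
    rr <- rdna[rdna$haplotype == h, ]
    sel <- d$chrom == rr$chrom & d$window_start >= rr$start &
      d$window_start < rr$end
    if (any(sel)) {
      ratio <- ratios[[rr$chrom]]
      d$depth[sel] <- rpois(sum(sel), cfg$mean_depth * ratio * rr$copies)
    }
    cbind(haplotype = h, d, stringsAsFactors = FALSE)
  }))
  rownames(depth) <- NULL

  manifest <- list(
    chromosomes = chroms[, c("chrom", "haplotype", "clade", "strain", "kind",
                             "group_index", "truth_group", "length", "telo5",
                             "telo3", "copy_ratio")],
    presence = presence_long(presence, chroms),
    divergences = list(core_between_clades = cfg$core_divergence,
                       core_within_clade = cfg$core_divergence_within,
                       ac = cfg$ac_divergence),
    sv_events = if (length(sv_rows)) do.call(rbind, sv_rows) else
      data.frame(type = character(0), haplotype = character(0),
                 chrom = character(0), group = integer(0), start = integer(0),
                 end = integer(0), size = integer(0)),
    ltr_elements = if (length(ltr_rows)) do.call(rbind, ltr_rows) else
      data.frame(element = character(0), haplotype = character(0),
                 chrom = character(0), group = integer(0), start = integer(0),
                 end = integer(0), ltr_len = integer(0),
                 internal_len = integer(0), age = numeric(0)),
    rdna = rdna,
    rate_r = cfg$rate_r
  )

  structure(list(sequences = sequences, genes = ann$genes,
                 repeats = ann$repeats, proteins = ann$proteins,
                 depth = depth, manifest = manifest, config = cfg),
            class = "genome_set")
}

# Deterministic truth labels: CCnn / ACnn by descending mean member length.
truth_group_labels <- function(chroms) {
  lab <- character(nrow(chroms))
  for (kind in c("core", "ac")) {
    sel <- chroms$kind == kind
    mean_len <- tapply(chroms$length[sel], chroms$group_index[sel], mean)
    ord <- names(sort(mean_len, decreasing = TRUE))
    prefix <- if (kind == "core") "CC" else "AC"
    new <- setNames(sprintf("%s%02d", prefix, seq_along(ord)), ord)
    lab[sel] <- new[as.character(chroms$group_index[sel])]
  }
  lab
}

presence_long <- function(presence, chroms) {
  grp_label <- unique(chroms[chroms$kind == "ac",
                             c("group_index", "truth_group")])
  out <- expand.grid(group_index = as.integer(sub("^G", "", rownames(presence))),
                     haplotype = colnames(presence),
                     stringsAsFactors = FALSE)
  out$present <- as.integer(presence[cbind(paste0("G", out$group_index),
                                           out$haplotype)])
  out$group <- grp_label$truth_group[match(out$group_index,
                                           grp_label$group_index)]
  out[order(out$group, out$haplotype), c("group", "haplotype", "present")]
}

#' @export
print.genome_set <- function(x, ...) {
  n_hap <- length(x$sequences)
  n_chr <- nrow(x$manifest$chromosomes)
  cat(sprintf("genome_set: %d haplotypes, %d chromosomes (%d core groups, %d accessory groups)\n",
              n_hap, n_chr, x$config$n_core_chroms,
              x$config$n_accessory_groups))
  cat(sprintf("  genes: %d   repeats: %d   depth windows: %d\n",
              nrow(x$genes), nrow(x$repeats), nrow(x$depth)))
  invisible(x)
}
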