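#' Greedy clustering of proteins into gene families
#'
#' Length-sorted greedy clustering: each protein joins the first existing
#' family whose representative it matches at `identity_min` similarity over
#' a compatible length (shorter/longer >= `coverage_min`), computed with a
#' k-mer-prefiltered banded match-count alignment; otherwise it founds a new
#' family. Families are then assigned the standard pangenome classes: core
#' (members in every genome), singleton (exactly one member gene), else
#' accessory; and a compartment from their members' chromosome classes
#' (AC-only / CC-only / mixed).
#'
#' @param proteins Data frame with `gene_id`, `genome`, `seq` and optionally
#'   `chrom_class` (`"core"` / `"accessory"` per gene).
#' @param identity_min Similarity threshold (matched fraction of the
#'   shorter sequence), default 0.6.
#' @param coverage_min Minimum shorter/longer length ratio, default 0.7.
#' @param kmer Prefilter k-mer size (amino acids).
#' @param min_shared_kmers Candidate families must share at least this many
#'   k-mers with the protein.
#' @return List with `genes` (gene_id, genome, family, class, compartment)
#'   and `families` (family, n_members, n_genomes, class, compartment).
#' @export
cluster_gene_families <- function(proteins, identity_min = 0.6,
                                  coverage_min = 0.7, kmer = 5L,
                                  min_shared_kmers = 2L) {
  if (nrow(proteins) == 0) stop("no proteins supplied")
  if (anyDuplicated(proteins$gene_id)) {
    stop("duplicate gene identifiers in `proteins`")
  }
  genomes <- unique(proteins$genome)
  ord <- order(-nchar(proteins$seq), proteins$gene_id)
  p <- proteins[ord, , drop = FALSE]

  index <- new.env(parent = emptyenv()) # k-mer -> integer vector of family ids
  reps <- character(0)
  fam_of <- integer(nrow(p))
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < kmer) return(character(0))
    unique(substring(s, seq_len(n - kmer + 1), seq_len(n - kmer + 1) + kmer - 1))
  }
  for (i in seq_len(nrow(p))) {
    s <- p$seq[i]
    km <- kmers_of(s)
    hit <- unlist(lapply(km, function(x) index[[x]]), use.names = FALSE)
    fam <- 0L
    if (length(hit) > 0) {
      tab <- table(hit)
      cand <- sort(as.integer(names(tab)[tab >= min_shared_kmers]))
      for (f in cand) {
        r <- reps[f]
        lens <- c(nchar(s), nchar(r))
        if (min(lens) / max(lens) < coverage_min) next
        m <- cpp_banded_matches(s, r, 16L)
        if (m / min(lens) >= identity_min) { fam <- f; break }
      }
    }
    if (fam == 0L) {
      reps <- c(reps, s)
      fam <- length(reps)
      for (x in km) index[[x]] <- c(index[[x]], fam)
    }
    fam_of[i] <- fam
  }

  genes <- data.frame(gene_id = p$gene_id, genome = p$genome,
                      family = sprintf("FAM%05d", fam_of),
                      stringsAsFactors = FALSE)
  n_members <- table(genes$family)
  n_genomes <- tapply(genes$genome, genes$family,
                      function(x) length(unique(x)))
  fam_ids <- names(n_members)
  cls <- ifelse(n_members[fam_ids] == 1, "singleton",
                ifelse(n_genomes[fam_ids] == length(genomes), "core",
                       "accessory"))
  comp <- rep(NA_character_, length(fam_ids))
  if ("chrom_class" %in% names(p)) {
    on_ac <- tapply(p$chrom_class == "accessory", genes$family, any)
    on_cc <- tapply(p$chrom_class == "core", genes$family, any)
    comp <- ifelse(on_ac[fam_ids] & on_cc[fam_ids], "mixed",
                   ifelse(on_ac[fam_ids], "AC-only", "CC-only"))
  }
  fam_df <- data.frame(family = fam_ids,
                       n_members = as.integer(n_members[fam_ids]),
                       n_genomes = as.integer(n_genomes[fam_ids]),
                       class = unname(cls), compartment = unname(comp),
                       stringsAsFactors = FALSE)
  genes$class <- fam_df$class[match(genes$family, fam_df$family)]
  genes$compartment <- fam_df$compartment[match(genes$family, fam_df$family)]
  genes <- genes[match(proteins$gene_id, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, families = fam_df)
}

#' Partition accessory-chromosome genes by homology to core-chromosome genes
#'
#' An accessory-chromosome gene is "shared" when it matches any
#' core-chromosome protein at the same similarity thresholds used for
#' family clustering; the remainder are AC-specific. Percentages are
#' reported to one decimal.
#'
#' @param ac_proteins,cc_proteins Data frames with `gene_id` and `seq`.
#' @param identity_min,coverage_min,kmer,min_shared_kmers As in
#'   [cluster_gene_families()].
#' @return List: `genes` (gene_id, shared flag), `n_shared`, `n_total`,
#'   `pct_shared`.
#' @export
shared_ac_cc_genes <- function(ac_proteins, cc_proteins, identity_min = 0.6,
                               coverage_min = 0.7, kmer = 5L,
                               min_shared_kmers = 2L) {
  if (nrow(ac_proteins) == 0) stop("empty accessory gene set")
  index <- new.env(parent = emptyenv())
  add_kmers <- function(s, id) {
    n <- nchar(s)
    if (n < kmer) return(invisible())
    for (x in unique(substring(s, seq_len(n - kmer + 1),
                               seq_len(n - kmer + 1) + kmer - 1))) {
      index[[x]] <- c(index[[x]], id)
    }
  }
  for (i in seq_len(nrow(cc_proteins))) add_kmers(cc_proteins$seq[i], i)

  shared <- vapply(seq_len(nrow(ac_proteins)), function(i) {
    s <- ac_proteins$seq[i]
    n <- nchar(s)
    if (n < kmer) return(FALSE)
    km <- unique(substring(s, seq_len(n - kmer + 1),
                           seq_len(n - kmer + 1) + kmer - 1))
    hit <- unlist(lapply(km, function(x) index[[x]]), use.names = FALSE)
    if (length(hit) == 0) return(FALSE)
    tab <- table(hit)
    cand <- as.integer(names(sort(tab, decreasing = TRUE)))
    cand <- cand[tab[as.character(cand)] >= min_shared_kmers]
    for (j in cand) {
      r <- cc_proteins$seq[j]
      lens <- c(n, nchar(r))
      if (min(lens) / max(lens) < coverage_min) next
      if (cpp_banded_matches(s, r, 16L) / min(lens) >= identity_min) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))

  list(genes = data.frame(gene_id = ac_proteins$gene_id, shared = shared,
                          stringsAsFactors = FALSE),
       n_shared = sum(shared), n_total = length(shared),
       pct_shared = pct_of(sum(shared), length(shared)))
}

#' Flag genes embedded within transposable-element sequence
#'
#' A gene is embedded when at least `overlap_min` (default 0.8) of its span
#' lies inside the union of TE intervals on its chromosome.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based, end-exclusive).
#' @param repeats Data frame with `chrom`, `start`, `end`.
#' @param overlap_min Minimum covered fraction of the gene span.
#' @return List: `genes` (gene_id, te_overlap, embedded), `n_embedded`,
#'   `pct_embedded` (one decimal, over the supplied genes).
#' @export
te_embedding <- function(genes, repeats, overlap_min = 0.8) {
  if (nrow(genes) == 0) {
    return(list(genes = data.frame(gene_id = character(0),
                                   te_overlap = numeric(0),
                                   embedded = logical(0)),
                n_embedded = 0L, pct_embedded = NA_real_))
  }
  frac <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    rr <- repeats[repeats$chrom == g$chrom, , drop = FALSE]
    if (nrow(rr) == 0) return(0)
    te <- IRanges::reduce(IRanges::IRanges(rr$start, rr$end - 1L))
    ov <- IRanges::intersect(te, IRanges::IRanges(g$start, g$end - 1L))
    sum(IRanges::width(ov)) / (g$end - g$start)
  }, numeric(1))
  embedded <- frac >= overlap_min
  list(genes = data.frame(gene_id = genes$gene_id, te_overlap = frac,
                          embedded = embedded, stringsAsFactors = FALSE),
       n_embedded = sum(embedded),
       pct_embedded = pct_of(sum(embedded), nrow(genes)))
}

#' Jukes-Cantor distance from an observed mismatch proportion
#'
#' `K = -(3/4) * log(1 - (4/3) * p)`, the substitution-saturation-corrected
#' divergence for uniform substitution; defined for `p` in `[0, 0.75)`.
#'
#' @param p Observed proportion of differing sites.
#' @return Corrected distance `K` (substitutions per site), `K >= p`.
#' @examples
#' jc_distance(0.002) # 0.0020027
#' @export
jc_distance <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 0.75)) {
    stop("`p` must be in [0, 0.75) (Jukes-Cantor saturation at 0.75)")
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Build an LTR pair record from two terminal-repeat sequences
#'
#' Compares the 5' and 3' LTR copies of an element: position-wise when they
#' are equal length, otherwise through a banded alignment (band 16), and
#' records the mismatch proportion `p`. Pairs with fewer than 100 aligned
#' bases are flagged low-confidence rather than rejected.
#'
#' @param ltr5,ltr3 Terminal repeat sequences.
#' @param element Optional element identifier.
#' @return Object of class `ltr_pair`: `element`, `aligned_len`,
#'   `mismatches`, `p`, `low_confidence`.
#' @export
ltr_pair <- function(ltr5, ltr3, element = NA_character_) {
  n5 <- nchar(ltr5); n3 <- nchar(ltr3)
  if (n5 == 0 || n3 == 0) stop("empty LTR sequence")
  if (n5 == n3) {
    aligned <- n5
    mism <- cpp_hamming(ltr5, ltr3)
  } else {
    aligned <- min(n5, n3)
    matches <- cpp_banded_matches(ltr5, ltr3, 16L)
    mism <- aligned - matches
  }
  p <- mism / aligned
  structure(list(element = element, aligned_len = aligned,
                 mismatches = mism, p = p,
                 low_confidence = aligned < 100),
            class = "ltr_pair")
}

#' Insertion age of an LTR retrotransposon
#'
#' The two terminal repeats are identical at insertion and diverge
#' independently at the neutral rate, so `T = K / (2r)` with `K` the
#' Jukes-Cantor-corrected divergence between them.
#'
#' @param pair An `ltr_pair` (or a bare mismatch proportion `p`).
#' @param r Neutral substitution rate in substitutions/site/year
#'   (default `2e-9`).
#' @return List: `age` (years, raw), `age_rounded` (nearest 10,000 years),
#'   `K`, `p`, `low_confidence`.
#' @examples
#' ltr_insertion_age(0.002)$age # about 500670 years
#' @export
ltr_insertion_age <- function(pair, r = 2e-9) {
  if (r <= 0) stop("`r` must be > 0")
  if (inherits(pair, "ltr_pair")) {
    p <- pair$p
    low <- pair$low_confidence
  } else {
    p <- pair
    low <- FALSE
  }
  K <- jc_distance(p)
  age <- K / (2 * r)
  list(age = age, age_rounded = round(age, -4), K = K, p = p,
       low_confidence = low)
}

#' Extract the terminal-repeat pair of a planted LTR element
#'
#' Slices the 5' and 3' LTR copies of an element out of a chromosome given
#' its insertion coordinates, as recorded in a simulation truth manifest.
#'
#' @param seq Chromosome sequence.
#' @param start Element start (1-based).
#' @param ltr_len,internal_len Element geometry (bp).
#' @param element Optional identifier.
#' @return An `ltr_pair`.
#' @export
ltr_pair_from_coords <- function(seq, start, ltr_len, internal_len,
                                 element = NA_character_) {
  l5 <- substr(seq, start, start + ltr_len - 1)
  s3 <- start + ltr_len + internal_len
  l3 <- substr(seq, s3, s3 + ltr_len - 1)
  ltr_pair(l5, l3, element)
}

#' Earliest genetic-exchange time per accessory group
#'
#' The maximum dated insertion age among a group's elements; groups with no
#' datable pair are flagged inestimable (`NA` age) rather than erroring.
#'
#' @param ages Named list (or vector split by group) of insertion ages in
#'   years.
#' @return Data frame: `group`, `n_elements`, `earliest_years`,
#'   `inestimable`.
#' @export
earliest_exchange_time <- function(ages) {
  rows <- lapply(names(ages), function(g) {
    v <- ages[[g]]
    v <- v[is.finite(v)]
    data.frame(group = g, n_elements = length(v),
               earliest_years = if (length(v)) max(v) else NA_real_,
               inestimable = length(v) == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-accessory-group origin evidence summary
#'
#' Aggregates the origin-analysis evidence into one table: gene counts by
#' pangenome class, genes shared with core chromosomes (count and percent),
#' the TE-embedded percentage of those shared genes, and the earliest dated
#' exchange time. The cross-clade shared accessory gene count is attached
#' as an attribute.
#'
#' @param gene_groups Data frame with `gene_id`, `group` (accessory group
#'   label) and optionally `clade`.
#' @param families `genes` table from [cluster_gene_families()].
#' @param shared `genes` table from [shared_ac_cc_genes()].
#' @param embedding `genes` table from [te_embedding()] (shared genes only).
#' @param exchange Result of [earliest_exchange_time()], or `NULL`.
#' @return Data frame, one row per accessory group.
#' @export
origin_summary <- function(gene_groups, families, shared, embedding = NULL,
                           exchange = NULL) {
  if (is.null(families) || is.null(shared)) {
    miss <- c("families", "shared")[c(is.null(families), is.null(shared))]
    stop("missing upstream stage(s): ", paste(miss, collapse = ", "))
  }
  m <- merge(gene_groups, families[, c("gene_id", "class")], by = "gene_id")
  m <- merge(m, shared, by = "gene_id", all.x = TRUE)
  m$shared[is.na(m$shared)] <- FALSE
  if (!is.null(embedding)) {
    m <- merge(m, embedding[, c("gene_id", "embedded")], by = "gene_id",
               all.x = TRUE)
  } else m$embedded <- NA

  rows <- lapply(split(m, m$group), function(df) {
    n <- nrow(df)
    n_shared <- sum(df$shared)
    emb <- df$embedded[df$shared]
    data.frame(
      group = df$group[1], n_genes = n,
      n_core = sum(df$class == "core"),
      n_accessory = sum(df$class == "accessory"),
      n_singleton = sum(df$class == "singleton"),
      n_shared_cc = n_shared,
      pct_shared_cc = pct_of(n_shared, n),
      pct_embedded = if (n_shared > 0 && !all(is.na(emb)))
        pct_of(sum(emb, na.rm = TRUE), n_shared) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(exchange)) {
    out <- merge(out, exchange[, c("group", "earliest_years", "inestimable")],
                 by = "group", all.x = TRUE)
  }
  rownames(out) <- NULL
  if ("clade" %in% names(m) && "family" %in% names(families)) {
    fam <- families$family[match(m$gene_id, families$gene_id)]
    n_clades <- tapply(m$clade, fam, function(x) length(unique(x)))
    attr(out, "cross_clade_shared") <-
      sum(n_clades == length(unique(m$clade)))
  }
  out
}
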