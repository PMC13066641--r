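# Gene models, protein sequences and repeat annotations for the simulated
# population. Gene-family structure is planted explicitly so that pangenome
# classification, AC<->CC shared-gene detection and TE embedding can be
# recovered against the truth:
#   - every core chromosome group carries a fixed pool of gene families
#     present in all haplotypes (protein divergence ~5% between clades, ~1%
#     within);
#   - accessory groups carry their own families (present only in carriers),
#     a planted fraction of which are recent copies of core-chromosome
#     families ("shared" genes), most of those embedded inside TE intervals;
#   - each accessory chromosome also carries a few strain-unique singletons.
# Repeat intervals are annotation-level: the simulator plants TE intervals
# with per-class composition, not literal repetitive sequence.

TE_CLASSES <- c("LTR/Ty3", "LTR/Copia", "TIR/Mutator", "TIR/CACTA",
                "helitron", "repeat_fragment")
TE_MIX_CC <- c(0.15, 0.12, 0.25, 0.20, 0.13, 0.15)
TE_MIX_AC <- c(0.35, 0.25, 0.08, 0.07, 0.10, 0.15)

simulate_annotations <- function(cfg, chroms, roster, presence, ac_groups,
                                 core_len, ac_len) {
  ncc <- cfg$n_core_chroms

  ## family pools ------------------------------------------------------------
  n_core_fam <- round(cfg$gene_density_cc * core_len / 1e5)
  core_anc_prot <- lapply(n_core_fam, function(n) {
    vapply(round(runif(n, 150, 400)), random_protein, character(1))
  })
  core_clade_prot <- lapply(seq_along(core_anc_prot), function(k) {
    lapply(seq_len(cfg$clades), function(cl) {
      vapply(core_anc_prot[[k]], mutate_protein, character(1), p = 0.05,
             USE.NAMES = FALSE)
    })
  })

  nac <- cfg$n_accessory_groups
  ac_pool <- lapply(seq_len(nac), function(g) {
    n_genes <- round(cfg$gene_density_ac * ac_len[g] / 1e5)
    n_sing <- max(1L, round(cfg$singleton_fraction * n_genes))
    n_slot <- max(1L, n_genes - n_sing)
    n_shared <- round(cfg$shared_cc_fraction * n_slot)
    # shared families point at a core family (k, j); their carriers get
    # recent copies of that clade's core protein
    shared_src <- if (n_shared > 0) {
      k <- sample.int(ncc, n_shared, replace = TRUE)
      j <- vapply(k, function(kk) sample.int(n_core_fam[kk], 1), integer(1))
      data.frame(k = k, j = j)
    } else data.frame(k = integer(0), j = integer(0))
    anc <- vapply(round(runif(n_slot, 150, 400)), random_protein, character(1))
    list(n_slot = n_slot, n_shared = n_shared, shared_src = shared_src,
         anc = anc)
  })

  gene_rows <- vector("list", nrow(chroms))
  prot_rows <- vector("list", nrow(chroms))
  repeat_rows <- vector("list", nrow(chroms))

  for (i in seq_len(nrow(chroms))) {
    h <- chroms$haplotype[i]
    cl <- chroms$clade[i]
    chrom <- chroms$chrom[i]
    L <- chroms$length[i]
    is_core <- chroms$kind[i] == "core"
    gidx <- chroms$group_index[i]
    density <- if (is_core) cfg$gene_density_cc else cfg$gene_density_ac
    introns_mean <- if (is_core) cfg$introns_per_gene_cc else cfg$introns_per_gene_ac

    n_genes <- round(density * L / 1e5)
    if (is_core) n_genes <- min(n_genes, n_core_fam[gidx])

    ## family assignment per gene slot
    if (is_core) {
      fam <- sprintf("CF%02d_%04d", gidx, seq_len(n_genes))
      prot <- vapply(seq_len(n_genes), function(j) {
        mutate_protein(core_clade_prot[[gidx]][[cl]][j], 0.01)
      }, character(1))
      shared <- rep(FALSE, n_genes)
      singleton <- rep(FALSE, n_genes)
      embedded <- rep(FALSE, n_genes)
    } else {
      pool <- ac_pool[[gidx]]
      n_sing <- max(1L, round(cfg$singleton_fraction * n_genes))
      n_slot <- min(max(0L, n_genes - n_sing), pool$n_slot)
      n_genes <- n_slot + n_sing
      slot_idx <- seq_len(n_slot)
      is_shared_slot <- slot_idx <= pool$n_shared
      fam <- character(n_genes)
      prot <- character(n_genes)
      for (j in slot_idx) {
        if (is_shared_slot[j]) {
          k <- pool$shared_src$k[j]; jj <- pool$shared_src$j[j]
          fam[j] <- sprintf("CF%02d_%04d", k, jj)
          prot[j] <- mutate_protein(core_clade_prot[[k]][[cl]][jj], 0.015)
        } else {
          fam[j] <- sprintf("AF%02d_%04d", gidx, j)
          prot[j] <- mutate_protein(pool$anc[j], 0.01)
        }
      }
      if (n_sing > 0) {
        sidx <- n_slot + seq_len(n_sing)
        fam[sidx] <- sprintf("SF_%s_%02d_%02d", h, gidx, seq_len(n_sing))
        prot[sidx] <- vapply(round(runif(n_sing, 150, 400)), random_protein,
                             character(1))
      }
      shared <- c(is_shared_slot, rep(FALSE, n_sing))
      singleton <- c(rep(FALSE, n_slot), rep(TRUE, n_sing))
      # planted TE embedding applies to the shared genes only
      n_shared_here <- sum(shared)
      n_emb <- round(cfg$te_embed_fraction * n_shared_here)
      embedded <- rep(FALSE, n_genes)
      embedded[which(shared)[seq_len(n_emb)]] <- TRUE
    }

    ## gene placement: one gene per equal-width slot, random offset
    if (n_genes > 0) {
      n_introns <- rpois(n_genes, introns_mean)
      n_exons <- n_introns + 1L
      span <- 250L * n_exons + 60L * n_introns
      slot <- L / n_genes
      slot_start <- floor((seq_len(n_genes) - 1L) * slot) + 1L
      offset <- floor(runif(n_genes) * pmax(1, floor(slot) - span))
      start <- pmin(slot_start + offset, pmax(1L, L - span))
      end <- start + span # 1-based, end-exclusive
      strand <- sample(c("+", "-"), n_genes, replace = TRUE)
      gene_id <- sprintf("%s.g%04d", chrom, seq_len(n_genes))
      gene_rows[[i]] <- data.frame(
        gene_id = gene_id, haplotype = h, chrom = chrom,
        start = as.integer(start), end = as.integer(end), strand = strand,
        n_exons = n_exons, family = fam, shared_cc = shared,
        embedded = embedded, singleton = singleton, stringsAsFactors = FALSE)
      prot_rows[[i]] <- data.frame(gene_id = gene_id, seq = prot,
                                   stringsAsFactors = FALSE)
    } else {
      gene_rows[[i]] <- NULL
      prot_rows[[i]] <- NULL
    }

    ## repeat intervals ------------------------------------------------------
    te_range <- if (is_core) cfg$te_fraction_cc else cfg$te_fraction_ac
    target_frac <- runif(1, te_range[1], te_range[2])
    mix <- if (is_core) TE_MIX_CC else TE_MIX_AC
    reps <- list()
    covered <- 0
    if (n_genes > 0 && any(embedded)) {
      gs <- gene_rows[[i]]
      for (j in which(embedded)) {
        s <- max(1L, gs$start[j] - 200L)
        e <- min(L + 1L, gs$end[j] + 200L)
        reps[[length(reps) + 1]] <- data.frame(
          haplotype = h, chrom = chrom, start = s, end = e,
          class = "LTR/Ty3", stringsAsFactors = FALSE)
        covered <- covered + (e - s)
      }
    }
    # non-embedded shared genes must stay TE-free: exclude their tiles
    tile <- 5000L
    grid <- seq(1L, L - tile, by = tile)
    if (n_genes > 0) {
      gs <- gene_rows[[i]]
      excl <- which(shared & !embedded)
      if (length(excl) > 0) {
        bad <- vapply(grid, function(ts) {
          any(gs$start[excl] < ts + tile & gs$end[excl] > ts)
        }, logical(1))
        grid <- grid[!bad]
      }
    }
    n_tiles <- max(0L, round((target_frac * L - covered) / tile))
    n_tiles <- min(n_tiles, length(grid))
    if (n_tiles > 0) {
      starts <- sort(sample(grid, n_tiles))
      reps[[length(reps) + 1]] <- data.frame(
        haplotype = h, chrom = chrom, start = starts, end = starts + tile,
        class = sample(TE_CLASSES, n_tiles, replace = TRUE, prob = mix),
        stringsAsFactors = FALSE)
    }
    repeat_rows[[i]] <- if (length(reps)) do.call(rbind, reps) else NULL
  }

  genes <- do.call(rbind, gene_rows)
  repeats <- do.call(rbind, repeat_rows)
  rownames(genes) <- rownames(repeats) <- NULL
  list(genes = genes,
       proteins = do.call(rbind, prot_rows),
       repeats = repeats)
}

#' Realized pangenome class of each planted gene family
#'
#' Classifies the families present in a simulated gene table by the standard
#' pangenome rule: families with members in every genome are core, families
#' with exactly one member gene are singletons, all others accessory. Used
#' as the truth reference in recovery tests.
#'
#' @param genes Gene table from a [simulate_genome_set()] result.
#' @param genomes Character vector of all haplotype identifiers.
#' @return Data frame with columns `family` and `class`.
#' @export
truth_family_classes <- function(genes, genomes) {
  n_members <- table(genes$family)
  n_genomes <- tapply(genes$haplotype, genes$family,
                      function(x) length(unique(x)))
  fam <- names(n_members)
  cls <- ifelse(n_members[fam] == 1, "singleton",
                ifelse(n_genomes[fam] == length(genomes), "core", "accessory"))
  data.frame(family = fam, class = unname(cls), stringsAsFactors = FALSE)
}
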