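#' Bottom-s k-mer sketch of a chromosome
#'
#' Hashes every distinct canonical k-mer (the lexicographic minimum of a
#' k-mer and its reverse complement, so sketches are strand-invariant) and
#' keeps the `sketch_size` smallest hash values. Sketches are the fast
#' pre-clustering primitive behind homology grouping.
#'
#' @param seq DNA string of length >= `k`.
#' @param k Odd k-mer size in 11..31 (default 17).
#' @param sketch_size Maximum sketch cardinality (default 5000).
#' @return Object of class `chrom_sketch`: sorted hash vector plus `k` and
#'   the distinct k-mer count.
#' @export
sketch_chromosome <- function(seq, k = 17L, sketch_size = 5000L) {
  if (k %% 2 != 1 || k < 11 || k > 31) stop("`k` must be odd and in 11..31")
  if (nchar(seq) < k) stop("sequence shorter than k")
  h <- cpp_sketch(seq, as.integer(k), as.integer(sketch_size))
  structure(list(hashes = h, k = as.integer(k), n = length(h)),
            class = "chrom_sketch")
}

#' Containment estimate between two sketches
#'
#' `|intersection| / |smaller sketch|`, an estimate of the fraction of the
#' smaller chromosome's k-mers present in the larger one. Near 1 for
#' identical sequences, about `(1 - p)^k` for homologs at per-site
#' divergence `p`, and near 0 for unrelated chromosomes.
#'
#' @param a,b `chrom_sketch` objects built with the same `k`.
#' @return Containment in `[0, 1]`.
#' @export
pairwise_containment <- function(a, b) {
  stopifnot(inherits(a, "chrom_sketch"), inherits(b, "chrom_sketch"))
  if (a$k != b$k) stop("sketches built with different k")
  if (a$n == 0 || b$n == 0) stop("empty sketch")
  cpp_sorted_intersect(a$hashes, b$hashes) / min(a$n, b$n)
}

#' Cluster chromosomes into homologous groups by sketch containment
#'
#' Builds the graph with an edge wherever pairwise containment reaches
#' `threshold` and takes single-linkage connected components as homology
#' groups. Single linkage maximizes recall of presence/absence detection;
#' over-merging is guarded by the near-zero containment floor of unrelated
#' chromosomes. A chromosome that bridges two otherwise-separate groups
#' (an articulation vertex whose removal splits its component, with
#' containment at least `secondary_threshold` to each side) is treated as a
#' fusion state: it receives primary membership in the side it covers best
#' and a flagged secondary membership in the other, and is counted once in
#' summaries.
#'
#' @param sketches Named list of `chrom_sketch` objects (names are
#'   chromosome identifiers).
#' @param threshold Containment needed to link two chromosomes.
#' @param secondary_threshold Minimum containment from a bridge chromosome
#'   to each side for a multi-membership call.
#' @return List with `membership` (data frame `chrom`, `group`, `role`
#'   where role is `"primary"` or `"secondary"`) and `containment` (the
#'   symmetric matrix).
#' @export
cluster_homologous_chromosomes <- function(sketches, threshold = 0.08,
                                           secondary_threshold = 0.3) {
  if (length(sketches) == 0) stop("no chromosomes to cluster")
  ks <- unique(vapply(sketches, `[[`, integer(1), "k"))
  if (length(ks) != 1) stop("sketches built with different k")
  ids <- sort(names(sketches)) # input-order invariance
  cm <- cpp_containment_matrix(lapply(ids, function(i) sketches[[i]]$hashes))
  dimnames(cm) <- list(ids, ids)

  adj <- cm >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  membership <- data.frame(chrom = ids, group = unname(comp),
                           role = "primary", stringsAsFactors = FALSE)

  ## fusion bridges: articulation vertices that split their component
  arts <- names(igraph::articulation_points(g))
  next_group <- max(comp) + 1L
  for (v in arts) {
    g2 <- igraph::delete_vertices(g, v)
    sub <- igraph::components(g2)$membership
    sides <- split(names(sub)[comp[names(sub)] == comp[v]],
                   sub[names(sub)[comp[names(sub)] == comp[v]]])
    sides <- sides[vapply(sides, length, integer(1)) > 0]
    if (length(sides) != 2) next
    cov <- vapply(sides, function(s) max(cm[v, s]), numeric(1))
    if (any(cov < secondary_threshold)) next
    primary_side <- which.max(cov)
    # split the component: each side becomes its own group
    for (si in seq_along(sides)) {
      gid <- if (si == 1) comp[v] else next_group
      membership$group[membership$chrom %in% sides[[si]]] <- gid
    }
    membership$group[membership$chrom == v] <-
      if (primary_side == 1) comp[v] else next_group
    sec_gid <- if (primary_side == 1) next_group else comp[v]
    membership <- rbind(membership, data.frame(
      chrom = v, group = sec_gid, role = "secondary",
      stringsAsFactors = FALSE))
    next_group <- next_group + 1L
  }
  rownames(membership) <- NULL
  list(membership = membership, containment = cm)
}

#' Classify homology groups as core or accessory by presence/absence
#'
#' A group is core when at least one member chromosome occurs in every
#' haplotype of the roster; any group missing from at least one haplotype is
#' accessory. Groups are labeled `CC01..` / `AC01..` by descending mean
#' primary-member length within each class. Secondary (fusion) memberships
#' count toward presence but not toward summary statistics.
#'
#' @param clustering Result of [cluster_homologous_chromosomes()] (or a
#'   compatible membership data frame).
#' @param chrom2hap Named character vector mapping chromosome id to
#'   haplotype id.
#' @param lengths Named numeric vector of chromosome lengths.
#' @param roster Character vector of all haplotype identifiers.
#' @return List with `chromosomes` (chrom, haplotype, group label, class,
#'   role), `groups` (label, class, n members, mean length, presence count)
#'   and `presence` (group x haplotype 0/1 matrix).
#' @export
classify_core_accessory <- function(clustering, chrom2hap, lengths, roster) {
  membership <- if (is.data.frame(clustering)) clustering else
    clustering$membership
  if (nrow(membership) == 0) stop("empty clustering")
  if (length(roster) == 0) stop("empty haplotype roster")
  if (length(roster) == 1) {
    warning("roster contains a single haplotype; every group is vacuously core")
  }
  membership$haplotype <- chrom2hap[membership$chrom]
  if (anyNA(membership$haplotype)) stop("chromosome without haplotype mapping")

  gids <- sort(unique(membership$group))
  info <- lapply(gids, function(gid) {
    rows <- membership[membership$group == gid, ]
    prim <- rows[rows$role == "primary", ]
    present_in <- unique(rows$haplotype)
    list(gid = gid,
         mean_len = mean(lengths[prim$chrom]),
         n_members = nrow(prim),
         is_core = all(roster %in% present_in),
         present_in = present_in)
  })
  is_core <- vapply(info, `[[`, logical(1), "is_core")
  mean_len <- vapply(info, `[[`, numeric(1), "mean_len")
  label <- character(length(gids))
  for (cls in c(TRUE, FALSE)) {
    sel <- which(is_core == cls)
    ord <- sel[order(-mean_len[sel], gids[sel])]
    label[ord] <- sprintf("%s%02d", if (cls) "CC" else "AC", seq_along(ord))
  }
  names(label) <- as.character(gids)

  membership$group_label <- label[as.character(membership$group)]
  membership$class <- ifelse(is_core[match(membership$group, gids)],
                             "core", "accessory")
  presence <- matrix(0L, nrow = length(gids), ncol = length(roster),
                     dimnames = list(label, roster))
  for (i in seq_along(info)) {
    presence[label[i], intersect(info[[i]]$present_in, roster)] <- 1L
  }
  groups <- data.frame(
    group = label,
    class = ifelse(is_core, "core", "accessory"),
    n_members = vapply(info, `[[`, integer(1), "n_members"),
    mean_length = mean_len,
    n_haplotypes = rowSums(presence),
    stringsAsFactors = FALSE)
  groups <- groups[order(groups$group), ]
  rownames(groups) <- NULL
  list(chromosomes = membership[, c("chrom", "haplotype", "group_label",
                                    "class", "role")],
       groups = groups, presence = presence)
}

#' Fragment-based average nucleotide identity between two sequences
#'
#' OrthoANI-style estimator: both sequences are cut into consecutive
#' `fragment_len` pieces; each fragment's best gapless placement in the
#' other sequence is found by shared-k-mer diagonal voting (both strands);
#' fragment pairs are retained when they map reciprocally and the best match
#' reaches `min_identity` over at least `min_aligned` of the fragment. The
#' reported ANI is the mean retained identity, in percent.
#'
#' @param query,target DNA strings, both at least `fragment_len` long.
#' @param fragment_len Fragment size (bp, default 1000).
#' @param min_identity Identity retention threshold (default 0.6).
#' @param min_aligned Aligned-fraction retention threshold (default 0.7).
#' @param seed_k Seed k-mer size for diagonal voting.
#' @return Object of class `ani_result`: list with `ani` (percent, `NA`
#'   when nothing is retained), `n_fragments` (retained count) and
#'   `coverage` (retained / total query fragments).
#' @export
fragment_ani <- function(query, target, fragment_len = 1000L,
                         min_identity = 0.6, min_aligned = 0.7,
                         seed_k = 13L) {
  if (nchar(query) < fragment_len || nchar(target) < fragment_len) {
    stop("both sequences must be at least `fragment_len` long")
  }
  fq <- cpp_fragment_hits(query, target, as.integer(fragment_len),
                          as.integer(seed_k), 5L, 3L)
  ft <- cpp_fragment_hits(target, query, as.integer(fragment_len),
                          as.integer(seed_k), 5L, 3L)
  ok_q <- !is.na(fq$best_identity) & fq$best_identity >= min_identity &
    fq$aligned_frac >= min_aligned
  ok_t <- !is.na(ft$best_identity) & ft$best_identity >= min_identity &
    ft$aligned_frac >= min_aligned
  # reciprocity: query fragment i hits target fragment j and j hits back i
  jt <- ifelse(ok_q, pmin(nrow(ft), pmax(1, floor(fq$tmid / fragment_len) + 1)), NA)
  back <- ifelse(!is.na(jt) & ok_t[jt],
                 pmin(nrow(fq), pmax(1, floor(ft$tmid[jt] / fragment_len) + 1)), NA)
  recip <- !is.na(back) & back == seq_len(nrow(fq))
  n <- sum(recip)
  ani <- if (n == 0) NA_real_ else {
    100 * mean((fq$best_identity[recip] + ft$best_identity[jt[recip]]) / 2)
  }
  if (n == 0) {
    warning("no fragment pairs retained; identity undefined (coverage 0)")
  }
  structure(list(ani = ani, n_fragments = n,
                 coverage = n / nrow(fq)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI: %s%% over %d reciprocal fragments (coverage %.2f)\n",
              ifelse(is.na(x$ani), "NA", sprintf("%.2f", x$ani)),
              x$n_fragments, x$coverage))
  invisible(x)
}

#' Median pairwise ANI within each homology group
#'
#' Computes [fragment_ani()] over (a sample of) member pairs of every group
#' and returns the per-group median, the statistic used to contrast core and
#' accessory sequence conservation.
#'
#' @param seqs Named character vector of all chromosome sequences.
#' @param chromosomes Data frame with `chrom`, `group_label`, `class`, `role`
#'   (from [classify_core_accessory()]).
#' @param max_pairs Maximum member pairs sampled per group.
#' @param seed Seed for the pair subsample.
#' @param ... Passed to [fragment_ani()].
#' @return Data frame `group`, `class`, `n_pairs`, `median_ani`.
#' @export
group_ani <- function(seqs, chromosomes, max_pairs = 8L, seed = 1L, ...) {
  prim <- chromosomes[chromosomes$role == "primary", ]
  groups <- sort(unique(prim$group_label))
  with_seed(seed, {
    rows <- lapply(groups, function(gl) {
      members <- prim$chrom[prim$group_label == gl]
      cls <- prim$class[prim$group_label == gl][1]
      if (length(members) < 2) {
        return(data.frame(group = gl, class = cls, n_pairs = 0L,
                          median_ani = NA_real_, stringsAsFactors = FALSE))
      }
      pairs <- utils::combn(members, 2)
      if (ncol(pairs) > max_pairs) {
        pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
      }
      vals <- apply(pairs, 2, function(pr) {
        suppressWarnings(fragment_ani(seqs[[pr[1]]], seqs[[pr[2]]], ...)$ani)
      })
      data.frame(group = gl, class = cls, n_pairs = ncol(pairs),
                 median_ani = median(vals, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
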