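#' Find alignment anchors between two sequences
#'
#' Seed-and-extend anchor discovery on both strands. In `"exact"` mode,
#' anchors are maximal exact matches of at least `min_anchor` bp (the
#' nucmer-style length threshold of 2000 excludes short chance matches). In
#' `"tolerant"` mode, seeds are extended gaplessly through mismatches with
#' an X-drop rule and kept when the anchor reaches `min_anchor` bp at
#' `min_identity` -- the mode of choice for homologs at percent-level
#' divergence where long exact runs are rare. All coordinates are 1-based
#' with exclusive ends, so printed length equals `end - start`.
#'
#' @param query,target DNA strings.
#' @param min_anchor Minimum anchor length (bp).
#' @param mode `"exact"` or `"tolerant"`.
#' @param min_identity Identity floor for tolerant anchors.
#' @param seed_k Seed k-mer size (tolerant mode; exact mode uses
#'   `min(31, min_anchor)`).
#' @param xdrop X-drop score margin for tolerant extension.
#' @return Data frame: `qstart`, `qend`, `tstart`, `tend`, `strand`
#'   (`+`/`-`), `length`, `identity`, sorted by `qstart`.
#' @export
find_anchors <- function(query, target, min_anchor = 2000L,
                         mode = c("exact", "tolerant"),
                         min_identity = 0.95, seed_k = 15L, xdrop = 50L) {
  mode <- match.arg(mode)
  if (nchar(query) == 0 || nchar(target) == 0) {
    return(empty_anchor_df())
  }
  k <- if (mode == "exact") min(31L, as.integer(min_anchor)) else
    as.integer(seed_k)
  out <- cpp_find_anchors(query, target, as.integer(min_anchor),
                          if (mode == "exact") 0L else 1L, k,
                          min_identity, as.integer(xdrop), 100L)
  out <- out[order(out$qstart, out$tstart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_anchor_df <- function() {
  data.frame(qstart = integer(0), qend = integer(0), tstart = integer(0),
             tend = integer(0), strand = character(0), length = integer(0),
             identity = numeric(0), stringsAsFactors = FALSE)
}

#' Chain collinear anchors into synteny blocks
#'
#' Partitions the anchors of one query-target pair into maximal runs that
#' are monotone on both sequences with consistent orientation; a gap larger
#' than `merge_gap` on either sequence starts a new block. Blocks are the
#' units drawn in synteny plots and consumed by [classify_sv()].
#'
#' @param anchors Anchor data frame from [find_anchors()].
#' @param merge_gap Maximum bridged gap (bp).
#' @return Data frame of blocks: `block`, `qstart`, `qend`, `tstart`,
#'   `tend`, `strand`, `n_anchors`, sorted by `qstart`.
#' @export
chain_anchors <- function(anchors, merge_gap = 20000L) {
  if (nrow(anchors) == 0) {
    return(data.frame(block = integer(0), qstart = integer(0),
                      qend = integer(0), tstart = integer(0),
                      tend = integer(0), strand = character(0),
                      n_anchors = integer(0), stringsAsFactors = FALSE))
  }
  a <- anchors[order(anchors$qstart, anchors$tstart), , drop = FALSE]
  blocks <- list()
  cur <- a[1, , drop = FALSE]
  cur_block <- list(qstart = cur$qstart, qend = cur$qend,
                    tstart = cur$tstart, tend = cur$tend,
                    strand = cur$strand, n = 1L)
  flush <- function(b) {
    blocks[[length(blocks) + 1]] <<- data.frame(
      qstart = b$qstart, qend = b$qend, tstart = b$tstart, tend = b$tend,
      strand = b$strand, n_anchors = b$n, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(a))[-1]) {
    x <- a[i, ]
    gq <- x$qstart - cur_block$qend
    joins <- x$strand == cur_block$strand && gq <= merge_gap && gq >= -1000
    if (joins) {
      gt <- if (x$strand == "+") x$tstart - cur_block$tend
            else cur_block$tstart - x$tend
      joins <- gt <= merge_gap && gt >= -1000
    }
    if (joins) {
      cur_block$qend <- max(cur_block$qend, x$qend)
      if (x$strand == "+") {
        cur_block$tend <- max(cur_block$tend, x$tend)
      } else {
        cur_block$tstart <- min(cur_block$tstart, x$tstart)
      }
      cur_block$n <- cur_block$n + 1L
    } else {
      flush(cur_block)
      cur_block <- list(qstart = x$qstart, qend = x$qend,
                        tstart = x$tstart, tend = x$tend,
                        strand = x$strand, n = 1L)
    }
  }
  flush(cur_block)
  out <- do.call(rbind, blocks)
  out <- out[order(out$qstart), , drop = FALSE]
  out <- cbind(block = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

default_sv_thresholds <- function() {
  list(inv_min = 10e3, term_min = 20e3, indel_min = 50e3,
       merge_gap = 20e3, fusion_cov = 0.5)
}

#' Classify structural variants from synteny blocks
#'
#' Types the four rearrangement classes between homologous chromosomes:
#' inversions (minority-orientation blocks of at least `inv_min`), terminal
#' losses (an unaligned terminus of at least `term_min` on one homolog
#' while the partner's corresponding terminus is aligned), large
#' insertions/deletions (an internal unaligned gap of at least `indel_min`
#' -- default 50 kb -- on one side only), and fusion/split events (one
#' chromosome whose blocks partition across two partner chromosomes, each
#' covered to at least `fusion_cov`). Coordinates are 1-based with
#' exclusive ends.
#'
#' @param chains Data frame of blocks for one or more homolog pairs; must
#'   carry `qname` and `tname` columns in addition to the columns of
#'   [chain_anchors()].
#' @param lengths Named vector with the length of every chromosome involved.
#' @param thresholds List overriding [default_sv_thresholds()] entries.
#' @return Data frame of events: `type`, `chrom`, `partner`, `start`,
#'   `end`, `size`, `detail`.
#' @export
classify_sv <- function(chains, lengths, thresholds = list()) {
  th <- utils::modifyList(default_sv_thresholds(), thresholds)
  if (any(unlist(th) <= 0)) stop("SV thresholds must be positive")
  if (!all(c("qname", "tname") %in% names(chains))) {
    stop("`chains` must carry qname and tname columns")
  }
  ev <- list()
  add <- function(type, chrom, partner, start, end, detail) {
    ev[[length(ev) + 1]] <<- data.frame(
      type = type, chrom = chrom, partner = partner,
      start = as.integer(start), end = as.integer(end),
      size = as.integer(end - start), detail = detail,
      stringsAsFactors = FALSE)
  }

  pairs <- unique(chains[, c("qname", "tname")])
  for (pi in seq_len(nrow(pairs))) {
    qn <- pairs$qname[pi]; tn <- pairs$tname[pi]
    b <- chains[chains$qname == qn & chains$tname == tn, , drop = FALSE]
    b <- b[order(b$qstart), , drop = FALSE]
    if (nrow(b) == 0) next
    qlen <- lengths[[qn]]; tlen <- lengths[[tn]]
    span <- b$qend - b$qstart
    major <- if (sum(span[b$strand == "+"]) >= sum(span[b$strand == "-"]))
      "+" else "-"

    # inversions: minority-orientation blocks
    for (i in which(b$strand != major & span >= th$inv_min)) {
      add("inversion", qn, tn, b$qstart[i], b$qend[i], "orientation_flip")
    }

    # internal one-sided gaps: insertion/deletion
    if (nrow(b) >= 2) {
      for (i in seq_len(nrow(b) - 1)) {
        gq <- b$qstart[i + 1] - b$qend[i]
        gt <- if (major == "+") b$tstart[i + 1] - b$tend[i]
              else b$tstart[i] - b$tend[i + 1]
        gq <- max(gq, 0); gt <- max(gt, 0)
        if (gq >= th$indel_min && gt < th$indel_min) {
          add("insertion_deletion", qn, tn, b$qend[i], b$qstart[i + 1],
              "present_in_query_only")
        } else if (gt >= th$indel_min && gq < th$indel_min) {
          ts <- if (major == "+") b$tend[i] else b$tend[i + 1]
          add("insertion_deletion", tn, qn, ts, ts + gt,
              "present_in_target_only")
        }
      }
    }

    # terminal losses
    q_pre <- min(b$qstart) - 1
    q_suf <- qlen - max(b$qend) + 1
    t_pre <- min(b$tstart) - 1
    t_suf <- tlen - max(b$tend) + 1
    term <- function(over, other, chrom, partner, start, end, which_end) {
      if (over >= th$term_min && other < th$term_min) {
        add("terminal_loss", chrom, partner, start, end,
            sprintf("%s_terminus_absent_from_%s", which_end, partner))
      }
    }
    if (major == "+") {
      term(q_pre, t_pre, qn, tn, 1, q_pre + 1, "5p")
      term(q_suf, t_suf, qn, tn, max(b$qend), qlen + 1, "3p")
      term(t_pre, q_pre, tn, qn, 1, t_pre + 1, "5p")
      term(t_suf, q_suf, tn, qn, max(b$tend), tlen + 1, "3p")
    } else {
      term(q_pre, t_suf, qn, tn, 1, q_pre + 1, "5p")
      term(q_suf, t_pre, qn, tn, max(b$qend), qlen + 1, "3p")
      term(t_pre, q_suf, tn, qn, 1, t_pre + 1, "5p")
      term(t_suf, q_pre, tn, qn, max(b$tend), tlen + 1, "3p")
    }
  }

  # fusion/split: one query chromosome covering two partner chromosomes
  for (qn in unique(chains$qname)) {
    b <- chains[chains$qname == qn, , drop = FALSE]
    cov <- vapply(split(b, b$tname), function(df) {
      sum(df$tend - df$tstart) / lengths[[df$tname[1]]]
    }, numeric(1))
    covered <- names(cov)[cov >= th$fusion_cov]
    if (length(covered) >= 2) {
      add("fusion_split", qn, paste(sort(covered), collapse = "+"),
          1, lengths[[qn]] + 1, "spans_two_partner_chromosomes")
    }
  }

  if (length(ev) == 0) {
    return(data.frame(type = character(0), chrom = character(0),
                      partner = character(0), start = integer(0),
                      end = integer(0), size = integer(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  # a fused chromosome necessarily leaves each partner with one unaligned
  # terminus; those are part of the fusion/split call, not separate losses
  fus <- out[out$type == "fusion_split", , drop = FALSE]
  if (nrow(fus) > 0) {
    for (i in seq_len(nrow(fus))) {
      parts <- strsplit(fus$partner[i], "+", fixed = TRUE)[[1]]
      drop <- out$type == "terminal_loss" &
        ((out$chrom == fus$chrom[i] & out$partner %in% parts) |
           (out$partner == fus$chrom[i] & out$chrom %in% parts))
      out <- out[!drop, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Anchor, chain and classify one homolog pair (or set)
#'
#' Convenience wrapper running [find_anchors()] and [chain_anchors()] for
#' every query-target combination and typing events with [classify_sv()].
#'
#' @param query Named character vector of query chromosome sequences.
#' @param target Named character vector of target chromosome sequences.
#' @param min_anchor,mode,merge_gap,thresholds Passed through.
#' @return List with `chains` and `events`.
#' @export
sv_scan <- function(query, target, min_anchor = 2000L, mode = "tolerant",
                    merge_gap = 20000L, thresholds = list()) {
  chains <- list()
  for (qn in names(query)) {
    for (tn in names(target)) {
      a <- find_anchors(query[[qn]], target[[tn]], min_anchor, mode)
      if (nrow(a) == 0) next
      ch <- chain_anchors(a, merge_gap)
      chains[[length(chains) + 1]] <- cbind(qname = qn, tname = tn, ch,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(chains) == 0) {
    return(list(chains = NULL, events = classify_sv(
      data.frame(qname = character(0), tname = character(0)),
      lengths = c(nchar(query), nchar(target)), thresholds)))
  }
  chains <- do.call(rbind, chains)
  lengths <- c(vapply(query, nchar, integer(1)),
               vapply(target, nchar, integer(1)))
  list(chains = chains,
       events = classify_sv(chains, lengths, thresholds))
}
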