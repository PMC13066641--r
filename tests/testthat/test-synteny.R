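test_that("anchors cover trivial identity and reverse-complement cases", {
  set.seed(31)
  q <- accessoryscan:::random_dna(100000)
  a <- find_anchors(q, q)
  expect_equal(nrow(a), 1)
  expect_equal(a$qstart, 1)
  expect_equal(a$length, 100000)
  expect_equal(a$strand, "+")

  b <- find_anchors(q, accessoryscan:::revcomp(q))
  expect_equal(nrow(b), 1)
  expect_equal(b$strand, "-")
  expect_equal(b$length, 100000)

  r <- accessoryscan:::random_dna(100000)
  expect_equal(nrow(find_anchors(q, r, 2000)), 0)
})

test_that("exact anchors equal the brute-force maximal-exact-match scan", {
  set.seed(32)
  for (rep in 1:3) {
    q <- accessoryscan:::random_dna(4000)
    seg1 <- substr(q, 501, 1200)    # forward repeat
    seg2 <- substr(q, 2001, 2600)   # planted in reverse complement
    t <- paste0(accessoryscan:::random_dna(700), seg1,
                accessoryscan:::random_dna(600),
                accessoryscan:::revcomp(seg2),
                accessoryscan:::random_dna(500))
    got <- find_anchors(q, t, min_anchor = 100)
    want <- bf_mems(q, t, 100)
    got <- got[order(got$qstart, got$tstart, got$strand),
               c("qstart", "qend", "tstart", "tend", "strand", "length")]
    rownames(got) <- NULL
    expect_equal(got, want)
    expect_equal(nrow(got), 2)
  }
})

test_that("chaining yields one block per collinear run and 3 for an inverted middle", {
  set.seed(33)
  a <- accessoryscan:::random_dna(15000)
  b <- accessoryscan:::random_dna(15000)
  c <- accessoryscan:::random_dna(15000)
  q <- paste0(a, b, c)
  t <- paste0(a, accessoryscan:::revcomp(b), c)
  an <- find_anchors(q, t, min_anchor = 1000)
  ch <- chain_anchors(an, merge_gap = 2000)
  expect_equal(nrow(ch), 3)
  expect_identical(ch$strand, c("+", "-", "+"))
  expect_lt(abs(ch$qstart[2] - 15001), 50)
  expect_lt(abs(ch$qend[2] - 30001), 50)

  single <- chain_anchors(find_anchors(q, q))
  expect_equal(nrow(single), 1)
  empty <- chain_anchors(find_anchors(q, accessoryscan:::random_dna(20000)))
  expect_equal(nrow(empty), 0)
})

test_that("each planted event type is recovered once with correct coordinates", {
  types <- c("inversion", "terminal_loss", "insertion_deletion", "fusion_split")
  for (i in seq_along(types)) {
    p <- simulate_homolog_pair(300e3, 0.005, sv = list(type = types[i]),
                               seed = 40 + i)
    res <- sv_scan(c(q = p$query), p$target)
    ev <- res$events
    expect_equal(nrow(ev), 1, info = types[i])
    expect_identical(ev$type, types[i])
    if (types[i] == "inversion") {
      expect_lt(abs(ev$start - p$truth$start), 2000)
      expect_lt(abs(ev$end - p$truth$end), 2000)
    }
    if (types[i] == "insertion_deletion") {
      expect_lt(abs(ev$size - p$truth$size), 2000)
    }
    if (types[i] == "terminal_loss") {
      expect_lt(abs(ev$size - p$truth$size), 2000)
    }
  }
})

test_that("divergence-only homolog pairs produce no events", {
  for (s in 1:3) {
    p <- simulate_homolog_pair(250e3, 0.01, seed = 50 + s)
    res <- sv_scan(c(q = p$query), p$target)
    expect_equal(nrow(res$events), 0)
  }
})

test_that("swapping query and target preserves indel events and coordinates", {
  p <- simulate_homolog_pair(300e3, 0.005,
                             sv = list(type = "insertion_deletion"), seed = 61)
  fwd <- sv_scan(c(q = p$query), p$target)$events
  rev <- sv_scan(p$target, c(q = p$query))$events
  expect_equal(nrow(fwd), nrow(rev))
  expect_identical(fwd$type, rev$type)
  expect_identical(fwd$chrom, rev$chrom) # the side carrying the sequence
  expect_lt(abs(fwd$start - rev$start), 20000)
  expect_identical(sort(unique(c(fwd$detail, rev$detail))),
                   c("present_in_query_only", "present_in_target_only"))
})

test_that("non-positive thresholds are rejected", {
  ch <- data.frame(qname = "q", tname = "t", block = 1L, qstart = 1L,
                   qend = 10L, tstart = 1L, tend = 10L, strand = "+",
                   n_anchors = 1L)
  expect_error(classify_sv(ch, c(q = 10, t = 10), list(inv_min = 0)),
               "positive")
})
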