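test_that("Jukes-Cantor distance matches the closed form and its inverse", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.002), 0.0020027, tolerance = 1e-4)
  expect_error(jc_distance(0.75), "0.75")
  expect_error(jc_distance(-0.01), "0.75")

  # numeric-inversion oracle: solve p back from K on a grid
  grid <- seq(0, 0.7, by = 0.01)
  for (p in grid) {
    K <- jc_distance(p)
    p_back <- stats::uniroot(function(x) jc_distance(x) - K,
                             c(0, 0.7499), tol = 1e-14)$root
    expect_lt(abs(p_back - p), 1e-12)
    expect_gte(K, p)
  }
  expect_true(all(diff(jc_distance(grid)) > 0))
})

test_that("insertion ages follow T = K/(2r) with the expected monotonicity", {
  expect_equal(ltr_insertion_age(0)$age, 0)
  a <- ltr_insertion_age(0.002)
  expect_equal(a$age, 500667.9, tolerance = 1e-6)
  expect_equal(round(a$age, -5), 5e5)
  b <- ltr_insertion_age(0.004)
  expect_equal(round(b$age, -4), 1.0e6) # saturation-corrected, ~1.003 Myr raw
  # strictly increasing in p, inversely proportional to r
  ps <- seq(0.0005, 0.01, by = 0.0005)
  ages <- vapply(ps, function(p) ltr_insertion_age(p)$age, numeric(1))
  expect_true(all(diff(ages) > 0))
  expect_equal(ltr_insertion_age(0.002, r = 4e-9)$age, a$age / 2)
  expect_error(ltr_insertion_age(0.002, r = 0), "r")
})

test_that("ltr_pair compares equal and unequal length repeats", {
  set.seed(70)
  l <- accessoryscan:::random_dna(3000)
  pr <- ltr_pair(l, l)
  expect_equal(pr$p, 0)
  m <- evolve_sequence(l, 0.01)
  pr <- ltr_pair(l, m)
  expect_lt(abs(pr$p - 0.01), 0.006)
  expect_false(pr$low_confidence)
  short <- ltr_pair(substr(l, 1, 50), substr(l, 1, 50))
  expect_true(short$low_confidence)
  # a 3' copy with a trimmed end still aligns through the banded path
  trimmed <- ltr_pair(l, substr(m, 1, 2990))
  expect_lt(trimmed$p, 0.02)
})

test_that("planted insertion ages are recovered within 15% (median of 50)", {
  set.seed(71)
  for (age in c(5e5, 1e6, 1.5e6)) {
    est <- replicate(50, {
      chr <- accessoryscan:::random_dna(15000)
      pl <- plant_ltr_element(chr, 5000, 4000, age, 2e-9)
      pr <- ltr_pair_from_coords(pl$seq, pl$truth$start, 5000, 4000)
      ltr_insertion_age(pr)$age
    })
    expect_lt(abs(median(est) - age) / age, 0.15)
  }
})

test_that("gene families recover planted pangenome classes", {
  gs <- small_sim()
  kind <- chrom_class_of(gs)
  prot <- data.frame(
    gene_id = gs$proteins$gene_id,
    genome = gs$genes$haplotype[match(gs$proteins$gene_id, gs$genes$gene_id)],
    seq = gs$proteins$seq,
    chrom_class = kind[gs$genes$chrom[match(gs$proteins$gene_id,
                                            gs$genes$gene_id)]],
    stringsAsFactors = FALSE)
  fam <- cluster_gene_families(prot)
  expect_equal(sum(table(fam$families$class)), nrow(fam$families))

  truth <- truth_family_classes(gs$genes, names(gs$sequences))
  truth_cls <- setNames(truth$class, truth$family)
  gene_truth <- unname(truth_cls[gs$genes$family[match(fam$genes$gene_id,
                                                       gs$genes$gene_id)]])
  expect_gte(mean(fam$genes$class == gene_truth), 0.99)

  # compartments: families with members on both chromosome classes are mixed
  shared_fams <- unique(fam$genes$family[prot$chrom_class == "accessory" &
                                           fam$genes$class == "core"])
  expect_true(all(fam$families$compartment[fam$families$family %in%
                                             shared_fams] == "mixed"))
  expect_error(cluster_gene_families(prot[c(1, 1), ]), "duplicate")
})

test_that("identical and unrelated proteins cluster as expected", {
  p <- data.frame(gene_id = c("a1", "b1", "c1", "d1"),
                  genome = c("g1", "g2", "g3", "g1"),
                  seq = c(rep(paste(rep("MKLVA", 50), collapse = ""), 3),
                          accessoryscan:::random_protein(250)),
                  stringsAsFactors = FALSE)
  fam <- cluster_gene_families(p)
  expect_equal(nrow(fam$families), 2)
  expect_identical(fam$genes$class[1:3], rep("core", 3))
  expect_identical(fam$genes$class[4], "singleton")
})

test_that("AC genes shared with core chromosomes are recovered exactly", {
  gs <- small_sim()
  kind <- chrom_class_of(gs)
  gk <- kind[gs$genes$chrom[match(gs$proteins$gene_id, gs$genes$gene_id)]]
  ac <- gs$proteins[gk == "accessory", ]
  cc <- gs$proteins[gk == "core", ]
  sh <- shared_ac_cc_genes(ac, cc)
  truth <- gs$genes$shared_cc[match(sh$genes$gene_id, gs$genes$gene_id)]
  expect_identical(sh$genes$shared, truth)
  expect_equal(sh$pct_shared, pct_of(sh$n_shared, sh$n_total))
  expect_error(shared_ac_cc_genes(ac[0, ], cc), "empty")
})

test_that("TE embedding flags follow the 80% overlap rule", {
  reps <- data.frame(chrom = "c", start = c(1000L, 5000L),
                     end = c(3000L, 6000L), class = "LTR/Ty3")
  genes <- data.frame(gene_id = c("inside", "outside", "partial"),
                      chrom = "c",
                      start = c(1200L, 10000L, 2500L),
                      end = c(2200L, 11000L, 4000L))
  emb <- te_embedding(genes, reps)
  expect_identical(emb$genes$embedded, c(TRUE, FALSE, FALSE))
  expect_equal(emb$genes$te_overlap[1], 1.0)

  gs <- small_sim()
  sel <- gs$genes[gs$genes$shared_cc, ]
  got <- te_embedding(sel, gs$repeats)
  expect_identical(got$genes$embedded, sel$embedded)
})

test_that("earliest exchange time is the maximum age, with inestimable flags", {
  res <- earliest_exchange_time(list(AC01 = c(0.2e6, 0.5e6, 1.0e6),
                                     AC02 = 7e5, AC03 = numeric(0)))
  expect_equal(res$earliest_years[res$group == "AC01"], 1.0e6)
  expect_equal(res$earliest_years[res$group == "AC02"], 7e5)
  expect_true(res$inestimable[res$group == "AC03"])
  expect_true(is.na(res$earliest_years[res$group == "AC03"]))
})

test_that("origin summary aggregates planted evidence correctly", {
  gene_groups <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    group = rep(c("AC01", "AC02"), each = 5),
    clade = rep(c(1, 2), each = 5))
  families <- data.frame(
    gene_id = gene_groups$gene_id,
    family = c(rep("F1", 3), "F2", "F3", rep("F4", 4), "F5"),
    class = c(rep("core", 3), "accessory", "singleton",
              rep("accessory", 4), "singleton"))
  shared <- data.frame(gene_id = gene_groups$gene_id,
                       shared = c(rep(TRUE, 3), rep(FALSE, 7)))
  embedding <- data.frame(gene_id = sprintf("g%02d", 1:3),
                          embedded = c(TRUE, TRUE, FALSE))
  exch <- earliest_exchange_time(list(AC01 = 1e6, AC02 = numeric(0)))
  out <- origin_summary(gene_groups, families, shared, embedding, exch)
  a1 <- out[out$group == "AC01", ]
  expect_equal(a1$n_genes, 5)
  expect_equal(a1$n_shared_cc, 3)
  expect_equal(a1$pct_shared_cc, 60.0)
  expect_equal(a1$pct_embedded, pct_of(2, 3))
  expect_equal(a1$earliest_years, 1e6)
  a2 <- out[out$group == "AC02", ]
  expect_equal(a2$n_shared_cc, 0)
  expect_equal(a2$pct_shared_cc, 0)
  expect_true(a2$inestimable)
  expect_error(origin_summary(gene_groups, NULL, shared), "families")
})
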