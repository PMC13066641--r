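test_that("sketches are deterministic and strand-canonical", {
  set.seed(7)
  s <- accessoryscan:::random_dna(20000)
  a <- sketch_chromosome(s)
  b <- sketch_chromosome(s)
  expect_identical(a$hashes, b$hashes)
  rc <- accessoryscan:::revcomp(s)
  expect_identical(sketch_chromosome(rc)$hashes, a$hashes)
  expect_error(sketch_chromosome("ACGT", k = 17), "shorter")
  expect_error(sketch_chromosome(s, k = 16), "odd")
})

test_that("containment separates identity, homology and unrelatedness", {
  set.seed(8)
  s <- accessoryscan:::random_dna(100000)
  a <- sketch_chromosome(s)
  expect_equal(pairwise_containment(a, a), 1.0)

  mut <- sketch_chromosome(evolve_sequence(s, 0.01, seed = 9))
  cont <- pairwise_containment(a, mut)
  expect_lt(abs(cont - 0.99^17), 0.05)

  r <- sketch_chromosome(accessoryscan:::random_dna(100000))
  expect_lt(pairwise_containment(a, r), 0.05)

  k15 <- sketch_chromosome(s, k = 15)
  expect_error(pairwise_containment(a, k15), "different k")
})

test_that("clustering handles identity, singletons and input order", {
  set.seed(10)
  base <- accessoryscan:::random_dna(50000)
  sketches <- list(
    h1.c1 = sketch_chromosome(base),
    h2.c1 = sketch_chromosome(base),
    h3.c1 = sketch_chromosome(base),
    h1.c2 = sketch_chromosome(accessoryscan:::random_dna(50000)))
  cl <- cluster_homologous_chromosomes(sketches)
  mem <- cl$membership
  expect_equal(length(unique(mem$group)), 2)
  g1 <- mem$group[mem$chrom == "h1.c1"]
  expect_true(all(mem$group[mem$chrom %in% c("h2.c1", "h3.c1")] == g1))
  expect_false(mem$group[mem$chrom == "h1.c2"] == g1)

  cl2 <- cluster_homologous_chromosomes(rev(sketches))
  expect_identical(cl$membership, cl2$membership)
  expect_error(cluster_homologous_chromosomes(list()), "no chromosomes")
})

test_that("a fusion chromosome is split out with a secondary membership", {
  set.seed(11)
  a <- accessoryscan:::random_dna(120000)
  b <- accessoryscan:::random_dna(120000)
  sketches <- list(
    h1.a = sketch_chromosome(a),
    h2.a = sketch_chromosome(evolve_sequence(a, 0.005)),
    h1.b = sketch_chromosome(b),
    h2.b = sketch_chromosome(evolve_sequence(b, 0.005)),
    h3.fused = sketch_chromosome(paste0(a, b)))
  cl <- cluster_homologous_chromosomes(sketches)
  mem <- cl$membership
  expect_equal(sum(mem$role == "secondary"), 1)
  expect_equal(mem$chrom[mem$role == "secondary"], "h3.fused")
  ga <- mem$group[mem$chrom == "h1.a" & mem$role == "primary"]
  gb <- mem$group[mem$chrom == "h1.b" & mem$role == "primary"]
  expect_false(ga == gb)
  fused <- mem[mem$chrom == "h3.fused", ]
  expect_setequal(fused$group, c(ga, gb))
})

test_that("core/accessory classification follows universal presence", {
  gs <- small_sim()
  truth <- gs$manifest$chromosomes
  res <- {
    seqs <- flatten_sequences(gs)
    sk <- lapply(seqs, sketch_chromosome)
    classify_core_accessory(cluster_homologous_chromosomes(sk),
                            setNames(truth$haplotype, truth$chrom),
                            setNames(truth$length, truth$chrom),
                            names(gs$sequences))
  }
  expect_true(all(res$groups$n_haplotypes[res$groups$class == "core"] ==
                    length(gs$sequences)))
  expect_true(all(res$groups$n_haplotypes[res$groups$class == "accessory"] <
                    length(gs$sequences)))
  # labels match the truth manifest exactly
  m <- merge(res$chromosomes[res$chromosomes$role == "primary", ],
             truth[, c("chrom", "truth_group")], by = "chrom")
  expect_identical(m$group_label, m$truth_group)
  # single-haplotype roster: vacuously core, with a warning
  one <- truth[truth$haplotype == truth$haplotype[1], ]
  sk1 <- lapply(flatten_sequences(gs)[one$chrom], sketch_chromosome)
  expect_warning(
    res1 <- classify_core_accessory(cluster_homologous_chromosomes(sk1),
                                    setNames(one$haplotype, one$chrom),
                                    setNames(one$length, one$chrom),
                                    unique(one$haplotype)),
    "single haplotype")
  expect_true(all(res1$groups$class == "core"))
})

test_that("fragment ANI matches construction and is symmetric", {
  set.seed(12)
  q <- accessoryscan:::random_dna(100000)
  self <- fragment_ani(q, q)
  expect_equal(self$ani, 100.0)
  expect_equal(self$coverage, 1.0)

  mut <- evolve_sequence(q, 0.02)
  ani_qt <- fragment_ani(q, mut)
  expect_lt(abs(ani_qt$ani - 98.0), 0.3)
  ani_tq <- fragment_ani(mut, q)
  expect_lt(abs(ani_qt$ani - ani_tq$ani), 0.5)

  r <- accessoryscan:::random_dna(100000)
  expect_warning(none <- fragment_ani(q, r), "no fragment pairs")
  expect_equal(none$coverage, 0)
  expect_true(is.na(none$ani))

  expect_error(fragment_ani("ACGT", q), "fragment_len")
})
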