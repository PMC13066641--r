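test_that("feature arithmetic: density, TE union, introns", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      start = seq(1, 999000, length.out = 200),
                      end = seq(1, 999000, length.out = 200) + 500,
                      n_exons = rep(4L, 200))
  fr <- chromosome_features("chr1", 1e6, genes)
  expect_equal(fr$gene_density, 20.0)
  expect_equal(fr$introns_per_gene, 3)

  # overlapping repeats are merged before the fraction is computed
  reps <- data.frame(chrom = "chr1", start = c(1L, 401L),
                     end = c(501L, 1001L), class = "LTR/Ty3")
  fr2 <- chromosome_features("chr1", 10000, repeats = reps)
  expect_equal(fr2$te_fraction, 0.1)

  # splitting an interval into abutting pieces changes nothing
  reps3 <- data.frame(chrom = "chr1", start = c(1L, 201L, 401L, 401L),
                      end = c(201L, 501L, 801L, 1001L), class = "LTR/Ty3")
  fr3 <- chromosome_features("chr1", 10000, repeats = reps3)
  expect_equal(fr3$te_fraction, 0.1)

  bad <- data.frame(gene_id = "g1", start = 5L, end = 20001L, n_exons = 1L)
  expect_error(chromosome_features("chr1", 10000, bad), "g1")
})

test_that("one-way ANOVA matches hand-computed F and handles degeneracy", {
  r <- compare_groups_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 0)
  r <- compare_groups_anova(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(r$F, 8.0)
  expect_equal(unname(r$df), c(1, 2))
  r <- compare_groups_anova(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_identical(r$F, Inf)
  expect_equal(r$p, 0)
  expect_error(compare_groups_anova(1:3, c("a", "a", "a")), "two groups")
})

test_that("ANOVA F agrees with the sums-of-squares oracle to 1e-9", {
  set.seed(14)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    ns <- sample(2:6, k, replace = TRUE)
    g <- rep(letters[1:k], ns)
    v <- rnorm(sum(ns), mean = as.integer(factor(g)))
    got <- compare_groups_anova(v, g)$F
    expect_lt(abs(got - bf_anova_f(v, g)), 1e-9)
  }
})

test_that("planted core/accessory feature contrasts are recovered", {
  gs <- small_sim()
  cls <- chrom_class_of(gs)
  lens <- setNames(gs$manifest$chromosomes$length,
                   gs$manifest$chromosomes$chrom)
  ft <- feature_table(lens, gs$genes, gs$repeats, gs$manifest$chromosomes)
  expect_gte(min(table(ft$class)), 10)

  mean_by <- function(col) tapply(ft[[col]], ft$class, mean)
  gd <- mean_by("gene_density")
  expect_lt(gd[["accessory"]], gd[["core"]])
  te <- mean_by("te_fraction")
  expect_gt(te[["accessory"]], te[["core"]])
  ig <- mean_by("introns_per_gene")
  expect_lt(ig[["accessory"]], ig[["core"]])

  for (col in c("gene_density", "te_fraction", "introns_per_gene")) {
    p <- compare_groups_anova(ft[[col]], ft$class)$p
    expect_lt(p, 0.01)
  }
  # accessory chromosomes are the smaller class
  expect_lt(mean_by("length")[["accessory"]], mean_by("length")[["core"]])
})

test_that("TE class composition shows the planted Ty3/Copia enrichment on ACs", {
  gs <- small_sim()
  comp <- te_class_composition(gs$repeats, chrom_class_of(gs))
  ty3 <- comp[comp$te_class == "LTR/Ty3", ]
  expect_gt(ty3$accessory, ty3$core)
  mut <- comp[comp$te_class == "TIR/Mutator", ]
  expect_lt(mut$accessory, mut$core)
  expect_lt(abs(sum(comp$core) - 1), 1e-9)
  expect_lt(abs(sum(comp$accessory) - 1), 1e-9)

  only <- data.frame(chrom = "c", start = 1L, end = 100L, class = "LTR/Ty3")
  comp1 <- te_class_composition(only, c(c = "accessory"))
  expect_equal(comp1$accessory[comp1$te_class == "LTR/Ty3"], 1.0)
  none <- te_class_composition(only[0, ], c(c = "accessory"))
  expect_true(all(none$accessory == 0))
})

test_that("size regression reproduces hand-computed OLS results", {
  r <- size_regression(0:10, 2 * (0:10) + 1)
  expect_equal(r$r_squared, 1.0)
  expect_equal(r$slope, 2)
  r <- size_regression(c(0, 1, 2), c(0, 1, 1))
  expect_equal(r$r_squared, 0.75)
  r <- size_regression(c(0, 1, 2), c(5, 5, 5))
  expect_equal(r$r_squared, 0)
  expect_true(r$zero_variance)
  expect_error(size_regression(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("accessory content correlates with genome size in the simulation", {
  gs <- default_sim()
  ch <- gs$manifest$chromosomes
  by_hap <- split(ch, ch$haplotype)
  gsize <- vapply(by_hap, function(df) sum(df$length), numeric(1))
  ac_size <- vapply(by_hap, function(df) sum(df$length[df$kind == "ac"]),
                    numeric(1))
  r <- size_regression(ac_size, gsize)
  expect_gt(r$r_squared, 0.5)
  expect_gt(r$slope, 0)
})
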