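test_that("a fixed seed gives byte-identical simulation outputs", {
  cfg <- sim_config(seed = 8, strains_per_clade = c(1L, 1L, 1L),
                    dikaryon_fraction = 1, n_core_chroms = 3L,
                    core_lengths = c(50e3, 70e3), n_accessory_groups = 3L,
                    ac_lengths = c(30e3, 40e3))
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  write_genome_set(simulate_genome_set(cfg), d1)
  write_genome_set(simulate_genome_set(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 2e7),
                     readBin(file.path(d2, f), "raw", n = 2e7),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config(ac_loss_prob = 1.5), "ac_loss_prob")
  expect_error(sim_config(core_lengths = c(-1, 10)), "core_lengths")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(te_fraction_ac = c(0.9, 0.2)), "te_fraction_ac")
})

test_that("evolve_sequence preserves length and hits the target divergence", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 100000, TRUE), collapse = "")
  expect_identical(evolve_sequence(s, 0), s)
  m <- evolve_sequence(s, 0.01, seed = 2)
  expect_equal(nchar(m), nchar(s))
  obs <- accessoryscan:::cpp_hamming(s, m) / nchar(s)
  expect_lt(abs(obs - 0.01), 0.002) # 3 sigma binomial bound
  expect_true(grepl("^[ACGT]+$", substr(m, 1, 1000)))
  expect_error(evolve_sequence(s, 0.8), "0.75")
  expect_error(evolve_sequence(s, -0.1), "0.75")
})

test_that("zero accessory divergence gives identical homologs within a clade", {
  cfg <- sim_config(seed = 5, strains_per_clade = c(2L, 1L, 1L),
                    dikaryon_fraction = 0, n_core_chroms = 2L,
                    core_lengths = c(40e3, 50e3), n_accessory_groups = 3L,
                    ac_lengths = c(30e3, 35e3), ac_divergence = 0,
                    ac_loss_prob = 0, p_missing_telomere = 0,
                    sv_plan = "none", ltr_plan = "none")
  gs <- simulate_genome_set(cfg)
  ch <- gs$manifest$chromosomes
  seqs <- flatten_sequences(gs)
  for (g in unique(ch$group_index[ch$kind == "ac"])) {
    members <- ch$chrom[ch$kind == "ac" & ch$group_index == g &
                          ch$clade == ch$clade[ch$kind == "ac" &
                                                 ch$group_index == g][1]]
    if (length(members) >= 2) {
      expect_identical(seqs[[members[1]]], seqs[[members[2]]])
    }
  }
})

test_that("planted absence removes the chromosome and is recorded", {
  gs <- small_sim()
  pres <- gs$manifest$presence
  ch <- gs$manifest$chromosomes
  absent <- pres[pres$present == 0, ]
  # at least one loss planted under the default loss probability
  expect_gt(nrow(absent), 0)
  for (i in seq_len(nrow(absent))) {
    sel <- ch$haplotype == absent$haplotype[i] &
      ch$truth_group == absent$group[i]
    expect_equal(sum(sel), 0)
  }
  # present entries all exist
  here <- pres[pres$present == 1, ]
  for (i in seq_len(nrow(here))) {
    sel <- ch$haplotype == here$haplotype[i] & ch$truth_group == here$group[i]
    expect_equal(sum(sel), 1)
  }
})

test_that("every chromosome appears exactly once in the manifest", {
  gs <- small_sim()
  ids <- unlist(lapply(gs$sequences, names), use.names = FALSE)
  expect_identical(sort(ids), sort(gs$manifest$chromosomes$chrom))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("planted LTR divergence matches the binomial expectation", {
  set.seed(42)
  chr <- accessoryscan:::random_dna(30000)
  p0 <- plant_ltr_element(chr, 10000, 5000, 0, 2e-9)
  pr0 <- ltr_pair_from_coords(p0$seq, p0$truth$start, 10000, 5000)
  expect_identical(pr0$mismatches, 0L)

  mism <- replicate(30, {
    pl <- plant_ltr_element(chr, 10000, 5000, 5e5, 2e-9)
    ltr_pair_from_coords(pl$seq, pl$truth$start, 10000, 5000)$mismatches
  })
  # expected ~20 mismatches (p ~ 0.002 over 10 kb), 3 sigma ~ 13
  expect_lt(abs(mean(mism) - 20), 13 / sqrt(30) * 3)
  expect_true(all(abs(mism - 20) <= 20)) # generous per-draw sanity bound
  expect_error(plant_ltr_element(chr, 1000, 500, 1e12, 2e-9), "saturation")
})

test_that("depth profile means track planted copy ratios", {
  lens <- setNames(rep(2000e3, 3), c("n", "zero", "double"))
  d <- simulate_depth_profile(lens, c(n = 1, zero = 0, double = 2),
                              mean_depth = 30, seed = 6)
  expect_equal(nrow(d), 3 * 2000)
  expect_true(all(d$depth[d$chrom == "zero"] == 0))
  m <- tapply(d$depth, d$chrom, mean)
  expect_lt(abs(m[["n"]] - 30), 3 * sqrt(30 / 2000))
  expect_lt(abs(m[["double"]] / m[["n"]] - 2), 0.05)
  expect_error(simulate_depth_profile(lens, mean_depth = -1), "mean_depth")
})

test_that("emitted gene counts recover the planted density on long chromosomes", {
  cfg <- sim_config(seed = 13, strains_per_clade = c(1L, 1L, 1L),
                    dikaryon_fraction = 0, n_core_chroms = 2L,
                    core_lengths = c(500e3, 600e3), n_accessory_groups = 3L,
                    ac_lengths = c(500e3, 550e3), sv_plan = "none",
                    ltr_plan = "none")
  gs <- simulate_genome_set(cfg)
  ch <- gs$manifest$chromosomes
  counts <- table(gs$genes$chrom)
  for (i in seq_len(nrow(ch))) {
    planted <- if (ch$kind[i] == "core") 36 else 16
    got <- as.integer(counts[ch$chrom[i]]) / (ch$length[i] / 1e5)
    expect_lt(abs(got - planted) / planted, 0.10)
  }
})

test_that("the truth manifest survives a JSON round trip", {
  gs <- default_sim() # carries planted SVs and LTR elements
  p <- tempfile(fileext = ".json")
  write_manifest(gs$manifest, p)
  m2 <- read_manifest(p)
  expect_equal(m2$presence$present, gs$manifest$presence$present)
  expect_equal(m2$presence$group, gs$manifest$presence$group)
  expect_equal(m2$chromosomes$copy_ratio, gs$manifest$chromosomes$copy_ratio)
  expect_equal(m2$chromosomes$truth_group, gs$manifest$chromosomes$truth_group)
  expect_equal(m2$ltr_elements$age, gs$manifest$ltr_elements$age)
  expect_equal(m2$sv_events$start, gs$manifest$sv_events$start)
  expect_equal(m2$rdna$copies, gs$manifest$rdna$copies)
  unlink(p)
})

test_that("planted structural variants lie inside their chromosomes", {
  gs <- default_sim()
  sv <- gs$manifest$sv_events
  ch <- gs$manifest$chromosomes
  expect_gt(nrow(sv), 0)
  for (i in seq_len(nrow(sv))) {
    len <- ch$length[ch$chrom == sv$chrom[i]]
    expect_gte(sv$start[i], 1)
    expect_lte(sv$start[i], len + 1)
  }
})
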