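---
title: "Characterizing accessory chromosomes from haploid assemblies"
author: "accessoryscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing accessory chromosomes from haploid assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accessoryscan)
```

## The problem

Many fungi carry, besides the core chromosomes (CCs) present in every
strain, a variable complement of accessory chromosomes (ACs; also called
dispensable, supernumerary or B chromosomes). ACs show presence/absence
polymorphism between strains, are typically small, transposon-rich and
gene-poor, vary in copy number during growth, and rearrange quickly even
while their sequences stay nearly identical between carriers. This package
implements the comparative-genomic workflow that characterizes such
chromosomes from a collection of complete haploid assemblies of a
dikaryotic fungus: presence/absence classification, feature contrasts,
depth-based copy-number estimation, structural-variant typing between
homologs, and an origin analysis based on shared genes, their
transposable-element (TE) context, and LTR-retrotransposon insertion
dating. A synthetic-population generator with a complete truth manifest
makes every stage testable by parameter recovery.

## Homology grouping and the core/accessory rule

Chromosomes from all haplotypes are clustered into homologous groups, and
a group is **core** when it has a member in every haplotype of the roster;
any group absent from at least one haplotype is **accessory**. Groups are
labeled `CC01..`/`AC01..` by descending mean member length, a
deterministic rule that also breaks ties in tests.

Clustering uses bottom-5000 sketches of canonical 17-mers and the
containment estimate `|A ∩ B| / |smaller sketch|`. For homologs at
per-site divergence *p* the expected containment is about `(1 - p)^17`:
roughly 0.92 at the ~0.5% divergence of AC homologs and 0.09–0.11 at the
12–13% divergence of cross-clade core homologs, while unrelated
chromosomes sit near `1e-4`. The linking threshold therefore defaults to
**0.08**: it must fall below the cross-clade core signal (0.09–0.11),
which still leaves it three orders of magnitude above the random floor,
and sketch sampling noise (s.d. ≈ 0.004 at sketch size 5000) keeps both
separations above 3σ. Components are single-linkage, chosen because
presence/absence detection needs recall; over-merging is guarded by the
near-zero containment of unrelated chromosomes.

A chromosome arising from a fusion links two otherwise-separate groups.
Such bridges are detected as articulation vertices whose removal splits
their component in two, with containment of at least 0.3 to each side;
the bridge gets primary membership on the side it covers best and a
flagged secondary membership on the other, counts toward presence in
both, and is counted once in summary statistics.

## Fragment ANI

`fragment_ani()` follows the fragment-based (OrthoANI-style) scheme: both
sequences are cut into consecutive 1-kb fragments; each fragment's best
gapless placement in the partner is found by shared 13-mer diagonal
voting on both strands; fragment pairs are kept when they map
reciprocally and the best match reaches 60% identity over at least 70% of
the fragment; the reported ANI is the mean retained identity. When
nothing is retained the identity is `NA` with coverage 0 and a warning —
never silently 0. On simulated populations the accessory-group median ANI
(≈99.5%) exceeds the core-group median (≈87–94%, depending on how many
sampled pairs cross clades), and the package asserts this as an ordering,
not as exact values.

## Telomeres and rDNA

Chromosome ends are scanned for tandem copies of the telomere units
`TAACCCCC` (5') and `TTAGGGGG` (3') within a 500-bp window; three
consecutive copies with at most one mismatch per 8-mer call a telomere.
The motif is fixed by the biology; the window, copy and mismatch
thresholds are package choices (small tandem counts avoid false negatives
at trimmed assembly ends) and are configurable. Completeness is then a
pure function of the two flags (`T2T`, `5p_only`, `3p_only`, `none`).

rDNA tandem arrays collapse in assemblies, so the copy number is
estimated as the depth of the unit interval divided by the single-copy
baseline depth. Note that in the simulator's depth tracks the collapsed
unit produces a visible spike: the chromosome carrying it has an elevated
chromosome-mean depth, exactly as in real data. The default copy-number
baseline (below) is a median across core chromosomes and is robust to
this one inflated chromosome; for per-chromosome work the manifest's rDNA
interval can be used to mask the unit.

## Copy number from window depths

Depth arrives as non-overlapping 1-kb windows. A chromosome's copy number
is its mean window depth over a baseline. The default baseline is the
**median of core-chromosome means** rather than the raw genome mean: in a
genome where large ACs are aneuploid (simultaneously 2.0×, 0.5× and 0×),
the genome mean itself shifts, and only re-anchoring on cores yields the
clean 2.0×/0.5×/0× readings; the literal genome-mean mode is retained as
an option. Events are called `absent` (< 0.05×), `loss` (< 1 − tol),
`gain` (> 1 + tol), else `normal`, with tol = 0.25 by default. One
boundary caveat: a planted 0.75× ratio sits exactly on the 0.25 boundary,
where Poisson noise makes the call indeterminate by construction;
recovery tests therefore evaluate calls at tol = 0.2, which separates the
planted grid {0, 0.5, 0.75, 1, 1.5, 2} from both boundaries. Estimates at
30× with ≥500 windows are within ±0.05 of truth (Poisson bound). The
per-window coefficient of variation is emitted alongside, as a summary of
the depth fluctuation seen in mixed cell populations.

## Synteny and structural variants

Anchors between homologs are found by seed-and-extend on both strands, in
two modes. `exact` reports maximal exact matches of ≥2000 bp (the
nucmer-style length threshold); at percent-level divergence exact 2-kb
runs are rare, so `tolerant` mode extends 15-mer seeds gaplessly through
mismatches under an X-drop rule and keeps anchors of ≥2000 bp at ≥95%
identity. Because the simulator introduces substitutions but no small
indels, homologous segments stay on one alignment diagonal and gapless
anchors lose nothing; on real data the tolerant mode corresponds to the
high-identity segments a gapped aligner would chain. Anchors are chained
into blocks that are monotone on both sequences with consistent
orientation, bridging gaps up to 20 kb.

Events are typed from the blocks of each homolog pair: **inversion** for
minority-orientation blocks ≥10 kb; **terminal loss** when one homolog
has an unaligned terminus ≥20 kb while the partner's corresponding
terminus is aligned; **insertion/deletion** for an internal one-sided gap
≥50 kb (the one threshold the source analysis states); **fusion/split**
when one chromosome's blocks cover ≥50% of each of two partner
chromosomes. A fused pair necessarily also shows one bare terminus per
partner; those are folded into the fusion call rather than reported as
losses. All coordinates are 1-based with exclusive ends, so a printed
span's length is `end − start`. The 10/20/50-kb thresholds approximate a
curation that was originally done on dot plots and are exposed as
configuration.

## Origins: shared genes, TE embedding, LTR dating

Proteins are clustered into gene families by length-sorted greedy
clustering: a protein joins the first family whose representative it
matches at ≥60% similarity (matched fraction of the shorter sequence,
via a k-mer-prefiltered banded match-count alignment, band 16) with a
length-ratio guard of 0.7; families are classed core / accessory /
singleton by the standard pangenome rules. The banded similarity is
computed in-package so the thresholds are explicit and the same 60%/70%
convention serves family clustering, AC↔CC shared-gene detection and the
fragment-ANI retention rule; `Biostrings::pairwiseAlignment` remains
available as an independent cross-check in tests. A gene is
**TE-embedded** when ≥80% of its span lies inside the union of repeat
intervals.

LTR elements are dated from their terminal repeats, identical at
insertion: with observed mismatch proportion *p*, the Jukes–Cantor
distance is `K = −(3/4) ln(1 − 4p/3)` and the age is `T = K/(2r)` at the
neutral rate `r = 2 × 10⁻⁹` substitutions/site/year, because the two
repeats diverge independently. Equal-length repeats are compared
position-wise; unequal lengths go through the banded alignment. Pairs
with <100 aligned bases are flagged low-confidence, not rejected. The
earliest exchange time of a group is the maximum member age; groups
without datable pairs are flagged inestimable. For `p = 0.002` the age is
~500,670 years, i.e. 500,000 at the reporting resolution of 100,000
years.

## The synthetic population

The generator's defaults emulate the study design the analysis assumes: a
3-clade population of 16 strains (5 monokaryons, 11 dikaryons that
contribute two haplotypes each — 27 haploid genomes), 9 core groups per
haplotype, 15 clade-restricted accessory groups with a 10% per-carrier
loss probability, pairwise core divergence 12% between clades and 0.5%
within, AC homolog divergence 0.5%, TE fractions drawn from 40–81% (AC)
vs 11–19% (CC), gene densities 36 vs 16 per 100 kb, 3.3 vs 2.1 introns
per gene, 14.2% of AC gene families planted as recent copies of CC genes
with 77.1% of those TE-embedded, ~4% singletons, telomere arrays of six
motif copies (3% of ends left bare), planted copy ratios
{1.5, 2.0, 0.5, 0} on one haplotype, rDNA units of 10 kb at 15–40 copies,
and LTR elements with ages of 0.2–1.7 Myr (every fifth group left without
intact elements, hence inestimable). Depth is Poisson per 1-kb window at
mean 30, matching the count nature of coverage and giving closed-form
recovery bounds.

Chromosome lengths are scaled down — cores 250–450 kb, ACs 120–300 kb —
so that the full pipeline (simulation, sketching, grouping, ANI, SV
typing, dating, pangenome clustering) runs in minutes on one CPU; all
divergence-driven statistics are length-invariant, and depth/dating
recovery bounds are stated in terms of window and repeat counts that the
scaled sizes still satisfy. The default structural-variant plan plants an
inversion, a terminal loss and a ≥50-kb deletion on accessory chromosomes
of three different clades. Fusion/split is exercised through dedicated
homolog-pair simulations rather than the default population: a
population-level fusion makes the truth homology partition genuinely
ambiguous (one chromosome belongs to two groups), which would turn the
exact presence-matrix recovery check into a convention test.

What the simulator does **not** emulate: repeat intervals are
annotations over ordinary random sequence (no literal repetitive DNA, so
there are no repeat-induced spurious anchors — real data would need
repeat-aware anchor filtering); substitutions are uniform with no small
indels; gene structures do not evolve; there is no recombination or
meiosis, and no read-level noise beyond Poisson window counts. Passing
recovery tests therefore demonstrates the correctness of the estimators
under their stated models, not robustness to every artifact of real
assemblies.

## Numerical conventions and degenerate inputs

* One-way ANOVA resolves degeneracy explicitly: all values identical →
  F = 0, p = 1; zero within-group variance with differing means →
  F = ∞, p = 0. The F statistic agrees with a hand-computed
  sums-of-squares oracle to 1e-9.
* OLS regression with constant response reports R² = 0 with a
  `zero_variance` flag; constant predictors are an error.
* Percentages are reported to one decimal (`pct_of()`), matching the
  field's reporting style.
* Group labels, clustering and all simulation outputs are deterministic
  for a fixed seed (byte-identical files), with chromosome identifiers
  sorted before clustering so input order cannot matter.

## A small worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 101, strains_per_clade = c(2L, 1L, 2L),
                  n_core_chroms = 3L, core_lengths = c(60e3, 90e3),
                  n_accessory_groups = 4L, ac_lengths = c(40e3, 60e3))
gs <- simulate_genome_set(cfg)

seqs <- unlist(gs$sequences)
names(seqs) <- unlist(lapply(gs$sequences, names))
sk <- lapply(seqs, sketch_chromosome)
cl <- cluster_homologous_chromosomes(sk)
truth <- gs$manifest$chromosomes
res <- classify_core_accessory(cl, setNames(truth$haplotype, truth$chrom),
                               setNames(truth$length, truth$chrom),
                               names(gs$sequences))
res$groups
```

## Known limitations

* Exact/tolerant anchors are gapless; breakpoint coordinates are
  resolved to within the seed/extension granularity (±2 kb in recovery
  tests), not to the base.
* The greedy family clustering is order-dependent by design
  (length-sorted, first match wins); at the planted divergences this
  recovers families exactly, but deeply diverged families could split.
* The copy-number module estimates whole-chromosome copy number only; it
  does not segment sub-chromosomal CNVs.
* Telomere discovery is motif-based; species with other repeat units
  need the motifs supplied.
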