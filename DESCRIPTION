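Package: accessoryscan
Title: Detection and Characterization of Fungal Accessory Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize accessory (dispensable, B) chromosomes in
    fungal genome collections from complete haploid assemblies. Chromosomes
    are clustered into homologous groups by k-mer sketch containment and
    classified core versus accessory by presence/absence polymorphism across
    strains; modules then contrast sequence features (gene density,
    transposable-element fraction, introns per gene, fragment-based average
    nucleotide identity), estimate chromosome copy number from normalized
    read depth in 1-kb windows, type structural variants between homologs
    (inversions, terminal losses, large indels, fusion/split events), and
    date LTR retrotransposon insertions from terminal-repeat divergence under
    the Jukes-Cantor model. A synthetic dikaryotic population generator with
    a full truth manifest supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
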