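#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a 60-column wrapped FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
}

# Derive exon coordinates from the fixed simulated gene geometry:
# contiguous 250-bp exons separated by 60-bp introns.
gene_exons <- function(start, n_exons) {
  lapply(seq_along(start), function(i) {
    s <- start[i] + (seq_len(n_exons[i]) - 1L) * 310L
    cbind(start = s, end = s + 250L)
  })
}

#' Write a gene table as GFF3 (gene/mRNA/exon features)
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_exons`; 1-based end-exclusive coordinates).
#' @param path Output path.
#' @export
write_gff3_genes <- function(genes, path) {
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  ex <- gene_exons(genes$start, genes$n_exons)
  n_ex <- genes$n_exons
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end - 1L),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  mrna_id <- paste0(genes$gene_id, ".t1")
  gr_mrna <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end - 1L),
    strand = genes$strand, type = "mRNA", ID = mrna_id,
    Parent = methods::as(as.list(genes$gene_id), "CharacterList"))
  exon_chrom <- rep(genes$chrom, n_ex)
  exon_parent <- rep(mrna_id, n_ex)
  exon_start <- unlist(lapply(ex, function(m) m[, "start"]))
  exon_end <- unlist(lapply(ex, function(m) m[, "end"]))
  gr_exon <- GenomicRanges::GRanges(
    exon_chrom, IRanges::IRanges(exon_start, exon_end - 1L),
    strand = rep(genes$strand, n_ex), type = "exon",
    ID = paste0(exon_parent, ".exon",
                unlist(lapply(n_ex, seq_len))),
    Parent = methods::as(as.list(exon_parent), "CharacterList"))
  gr_gene$Parent <- methods::as(rep(list(character(0)), length(gr_gene)),
                                "CharacterList")
  all <- c(gr_gene, gr_mrna, gr_exon)
  all <- all[order(GenomicRanges::seqnames(all),
                   GenomicRanges::start(all),
                   match(all$type, c("gene", "mRNA", "exon")))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file into the package gene-table layout
#'
#' @param path GFF3 path.
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (end-exclusive),
#'   `strand`, `n_exons`.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  mrna <- gr[gr$type == "mRNA"]
  exons <- gr[gr$type == "exon"]
  mrna_parent <- vapply(mrna$Parent, `[`, character(1), 1)
  exon_parent <- vapply(exons$Parent, `[`, character(1), 1)
  exon_gene <- mrna_parent[match(exon_parent, mrna$ID)]
  n_exons <- table(exon_gene)
  data.frame(
    gene_id = genes$ID,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes) + 1L,
    strand = as.character(GenomicRanges::strand(genes)),
    n_exons = as.integer(n_exons[genes$ID]),
    stringsAsFactors = FALSE)
}

#' Write repeat intervals as BED6 with the TE class in the name field
#' @param repeats Repeat table (`chrom`, `start`, `end`, `class`; 1-based
#'   end-exclusive).
#' @param path Output path.
#' @export
write_bed_repeats <- function(repeats, path) {
  gr <- GenomicRanges::GRanges(
    repeats$chrom, IRanges::IRanges(repeats$start, repeats$end - 1L),
    strand = "+")
  gr$name <- repeats$class
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BED repeat annotations into the package repeat-table layout
#' @param path BED path.
#' @return Data frame `chrom`, `start`, `end` (end-exclusive), `class`.
#' @export
read_bed_repeats <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr) + 1L,
    class = gr$name, stringsAsFactors = FALSE)
}

#' Write a depth track TSV (`chrom`, `window_start`, `depth`)
#' @param depth Depth data frame.
#' @param path Output path.
#' @export
write_depth_tsv <- function(depth, path) {
  write.table(depth[, c("chrom", "window_start", "depth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation truth manifest (JSON)
#' @param manifest Manifest list from a `genome_set`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a truth manifest written by [write_manifest()]
#' @param path JSON path.
#' @return Manifest list with data-frame components restored.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a complete simulated genome set to a directory
#'
#' Emits, per haplotype: `<hap>.fasta` (60-column), `<hap>.gff3`,
#' `<hap>.repeats.bed`, `<hap>.depth.tsv`, `<hap>.proteins.fasta`; plus
#' `manifest.json` and `config.json` at the top level. Output is
#' byte-deterministic for a fixed simulation seed.
#'
#' @param gs A `genome_set` from [simulate_genome_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(gs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (h in names(gs$sequences)) {
    write_fasta(gs$sequences[[h]], file.path(dir, paste0(h, ".fasta")))
    write_gff3_genes(gs$genes[gs$genes$haplotype == h, , drop = FALSE],
                     file.path(dir, paste0(h, ".gff3")))
    write_bed_repeats(gs$repeats[gs$repeats$haplotype == h, , drop = FALSE],
                      file.path(dir, paste0(h, ".repeats.bed")))
    write_depth_tsv(gs$depth[gs$depth$haplotype == h, , drop = FALSE],
                    file.path(dir, paste0(h, ".depth.tsv")))
    prot <- gs$proteins[gs$proteins$gene_id %in%
                          gs$genes$gene_id[gs$genes$haplotype == h], ]
    px <- Biostrings::AAStringSet(setNames(prot$seq, prot$gene_id))
    Biostrings::writeXStringSet(px, file.path(dir, paste0(h, ".proteins.fasta")),
                                width = 60L)
  }
  write_manifest(gs$manifest, file.path(dir, "manifest.json"))
  cfg <- gs$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a generic tab-separated table
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
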