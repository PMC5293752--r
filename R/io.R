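## Readers and writers for the plain-text interchange formats: FASTA
## (Biostrings), GFF3 (rtracklayer; 1-based closed per the format), TSV
## tables and a ground-truth JSON.

#' Write / read a genome FASTA
#' @param genome named `DNAStringSet`.
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write gene models as GFF3
#'
#' One `gene` feature per row of the annotation, with `ID` and
#' `exon_length` attributes. GFF3 coordinates are 1-based closed, matching
#' the annotation table.
#'
#' @param annotation gene table (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `exon_length`).
#' @param path file path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$exon_length <- annotation$exon_length
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Returns the annotation table used throughout the package; the TSS is
#' derived from the strand (start of `+` genes, end of `-` genes). The
#' `exon_length` attribute is used when present, otherwise the gene width.
#'
#' @param path GFF3 file.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "gene"]
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("gene(s) without strand in ", path)
  exon_length <- S4Vectors::mcols(gr)$exon_length
  if (is.null(exon_length)) exon_length <- GenomicRanges::width(gr)
  data.frame(gene_id = as.character(S4Vectors::mcols(gr)$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start, end = end, strand = strand,
             tss = ifelse(strand == "+", start, end),
             exon_length = as.integer(exon_length),
             stringsAsFactors = FALSE)
}

#' Write / read a gene count matrix as TSV
#'
#' Layout: a `gene_id` column followed by one column per library.
#' @param counts integer matrix with gene rownames.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Write a DEG table as TSV
#' @param degs a `deg_set`.
#' @param path file path.
#' @export
write_deg_tsv <- function(degs, path) {
  out <- data.frame(degs, comparison = attr(degs, "comparison"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic study to a directory
#'
#' Writes every pipeline input as plain text: `genome.fasta`,
#' `annotation.gff3`, `counts.tsv`, `motif_catalog.tsv`, `go_map.tsv`,
#' `tf_families.tsv`, `qpcr.tsv`, `gravitropism.tsv` and `truth.json`.
#'
#' @param study a `sim_study` object.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_genome_fasta(study$genome, fp("genome.fasta"))
  write_annotation_gff3(study$annotation, fp("annotation.gff3"))
  write_counts_tsv(study$counts, fp("counts.tsv"))
  tsv <- function(x, f) utils::write.table(x, fp(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(study$catalog, "motif_catalog.tsv")
  tsv(study$go_map, "go_map.tsv")
  tsv(study$tf_map, "tf_families.tsv")
  tsv(study$qpcr, "qpcr.tsv")
  tsv(study$gravitropism, "gravitropism.tsv")
  truth <- study$truth
  truth$cluster_labels <- as.list(truth$cluster_labels)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
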