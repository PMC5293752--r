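IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

check_iupac <- function(motif) {
  motif <- toupper(as.character(motif))
  if (length(motif) != 1 || is.na(motif) || nchar(motif) == 0)
    stop("motif must be a single non-empty string")
  letters <- strsplit(motif, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_EXPAND))
  if (length(bad))
    stop("invalid IUPAC letter(s) in motif ", motif, ": ",
         paste(unique(bad), collapse = ", "))
  motif
}

#' Extract strand-aware promoter sequences
#'
#' Returns, for every gene, the `length` bp immediately upstream of its
#' transcription start site on the coding strand: for a `+` strand gene with
#' TSS at 1-based position `t`, bases `[t - length, t - 1]`; for a `-`
#' strand gene the reverse complement of `[t + 1, t + length]`. Promoters
#' truncated by a contig edge are clipped and flagged. Promoters are not
#' masked against neighbouring gene bodies.
#'
#' @param genome a named [Biostrings::DNAStringSet] of contigs.
#' @param annotation data.frame with columns `gene_id`, `chrom`, `strand`
#'   and `tss` (1-based), e.g. from [sim_annotation()] or
#'   [read_annotation_gff3()].
#' @param length promoter length in bp (default 1000).
#' @return A `promoter_set`: list with `seq` (a `DNAStringSet` named by gene
#'   id, promoter in 5'->3' orientation of the gene) and `coords`
#'   (data.frame `gene_id`, `chrom`, `start`, `end` 1-based inclusive,
#'   `strand`, `clipped`).
#' @export
extract_promoters <- function(genome, annotation, length = 1000) {
  if (length < 1) stop("promoter length must be positive")
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  miss <- setdiff(unique(annotation$chrom), names(genome))
  if (base::length(miss))
    stop("gene(s) on contig(s) missing from genome: ",
         paste(miss, collapse = ", "))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  tss <- annotation$tss
  plus <- annotation$strand == "+"
  start <- ifelse(plus, pmax(1, tss - length), tss + 1)
  end <- ifelse(plus, tss - 1, pmin(clen[annotation$chrom], tss + length))
  if (any(end < start))
    stop("gene(s) with no upstream sequence at all: ",
         paste(annotation$gene_id[end < start], collapse = ", "))
  clipped <- (end - start + 1) < length
  seqs <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    s <- Biostrings::subseq(genome[[annotation$chrom[i]]], start[i], end[i])
    if (!plus[i]) s <- Biostrings::reverseComplement(s)
    seqs[[i]] <- s
  }
  seq <- Biostrings::DNAStringSet(seqs)
  names(seq) <- annotation$gene_id
  coords <- data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
                       start = start, end = end, strand = annotation$strand,
                       clipped = clipped, stringsAsFactors = FALSE,
                       row.names = NULL)
  structure(list(seq = seq, coords = coords), class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("Promoter set:", base::length(x$seq), "promoters;",
      sum(x$coords$clipped), "clipped at contig edges\n")
  invisible(x)
}

#' Match an IUPAC motif against a sequence
#'
#' Sliding exact match of a degenerate IUPAC consensus; overlapping
#' occurrences are all counted. With `both_strands` the reverse complement
#' of the motif is also scanned, so carrier status is orientation-agnostic
#' (the convention for plant cis-element catalogues).
#'
#' @param sequence a character string or [Biostrings::DNAString].
#' @param motif IUPAC consensus string (e.g. `"ATATT"`, `"WTTSSCGG"`).
#' @param both_strands scan both orientations (default TRUE).
#' @return List with `count` (total occurrences) and `carrier`
#'   (`count >= 1`).
#' @examples
#' match_iupac("GGATATTGG", "ATATT")$count  # 1
#' @export
match_iupac <- function(sequence, motif, both_strands = TRUE) {
  motif <- check_iupac(motif)
  subj <- if (methods::is(sequence, "DNAString")) sequence
          else Biostrings::DNAString(toupper(as.character(sequence)))
  cnt <- Biostrings::countPattern(motif, subj, fixed = FALSE)
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    cnt <- cnt + Biostrings::countPattern(rc, subj, fixed = FALSE)
  }
  list(count = cnt, carrier = cnt >= 1)
}

#' Carrier table: which promoters carry which motifs
#'
#' Scans every promoter against every motif of a catalogue and records
#' presence/absence (carrier status); per-motif occurrence counts are kept
#' as an attribute but enrichment works on carriers, matching how the study
#' reports "promoters of N DEGs".
#'
#' @param promoters a `promoter_set` from [extract_promoters()], or a named
#'   `DNAStringSet`.
#' @param catalog data.frame with columns `motif_id` and `iupac`.
#' @param both_strands scan both orientations (default TRUE).
#' @return Logical gene x motif matrix; attribute `"counts"` holds the
#'   integer occurrence matrix.
#' @export
carrier_table <- function(promoters, catalog, both_strands = TRUE) {
  seqs <- if (inherits(promoters, "promoter_set")) promoters$seq else promoters
  if (!all(c("motif_id", "iupac") %in% names(catalog)))
    stop("`catalog` needs columns motif_id and iupac")
  counts <- matrix(0L, base::length(seqs), nrow(catalog),
                   dimnames = list(names(seqs), catalog$motif_id))
  for (j in seq_len(nrow(catalog))) {
    motif <- check_iupac(catalog$iupac[j])
    cnt <- Biostrings::vcountPattern(motif, seqs, fixed = FALSE)
    if (both_strands) {
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(motif)))
      cnt <- cnt + Biostrings::vcountPattern(rc, seqs, fixed = FALSE)
    }
    counts[, j] <- cnt
  }
  structure(counts >= 1L, counts = counts)
}

#' Write promoters as a BED file (0-based half-open)
#'
#' @param promoters a `promoter_set`.
#' @param path output file.
#' @export
write_promoter_bed <- function(promoters, path) {
  co <- promoters$coords
  bed <- data.frame(chrom = co$chrom, start = co$start - 1L, end = co$end,
                    name = co$gene_id, score = 0L, strand = co$strand)
  if (any(bed$start < 0)) stop("negative BED coordinate")  # cannot happen
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
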