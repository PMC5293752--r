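## Synthetic-data generators emulating the three-library melatonin study
## design (water control M0, 10 and 20 umol treatments M10/M20), with
## recorded ground truth for recovery testing.

#' Simulate a genome with non-overlapping gene models
#'
#' Lays `n_genes` gene models on a single random chromosome, alternating
#' strands at random, with enough clear sequence on each gene's upstream
#' side that a full promoter can always be extracted. Coordinates are
#' 1-based inclusive; the TSS is `start` for `+` strand genes and `end` for
#' `-` strand genes.
#'
#' @param n_genes number of genes (>= 0).
#' @param chrom_length chromosome length in bp; by default sized to fit the
#'   requested genes with both-side promoter clearance and spacing.
#' @param promoter_length clear upstream bp guaranteed per gene (default
#'   1000).
#' @param gene_length integer range (min, max) of exon lengths, sampled
#'   uniformly (default 1200-1800).
#' @param spacer bp between gene blocks (default 100).
#' @param chrom_name contig name (default `"chr1"`).
#' @param seed optional integer seed; identical seeds give byte-identical
#'   genomes and annotations.
#' @return List with `genome` (a named `DNAStringSet`) and `annotation`
#'   (data.frame `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`,
#'   `exon_length`).
#' @export
sim_annotation <- function(n_genes, chrom_length = NULL,
                           promoter_length = 1000,
                           gene_length = c(1200, 1800), spacer = 100,
                           chrom_name = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  block <- 2 * promoter_length + gene_length[2] + spacer
  if (is.null(chrom_length))
    chrom_length <- max(n_genes * block + promoter_length, 1000)
  need <- n_genes * (promoter_length + gene_length[1])
  if (need > chrom_length)
    stop("infeasible packing: ", n_genes, " genes need at least ", need,
         " bp but chrom_length is ", chrom_length,
         " (short by ", need - chrom_length, " bp)")
  if (n_genes > 0 && n_genes * block + promoter_length > chrom_length)
    stop("infeasible packing with both-side promoter clearance: need ",
         n_genes * block + promoter_length, " bp, have ", chrom_length)
  genome_seq <- paste(sample(c("A", "C", "G", "T"), chrom_length,
                             replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- chrom_name
  if (n_genes == 0) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), tss = integer(),
                      exon_length = integer(), stringsAsFactors = FALSE)
    return(list(genome = genome, annotation = ann))
  }
  len <- sample(seq(gene_length[1], gene_length[2]), n_genes, replace = TRUE)
  offset <- cumsum(c(0, rep(block, n_genes - 1)))
  start <- offset + promoter_length + 1
  end <- start + len - 1
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  ann <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = chrom_name, start = start, end = end, strand = strand,
    tss = ifelse(strand == "+", start, end),
    exon_length = len, stringsAsFactors = FALSE)
  list(genome = genome, annotation = ann)
}

## one concrete (non-degenerate) instance of an IUPAC consensus
expand_iupac_once <- function(motif) {
  letters <- strsplit(check_iupac(motif), "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- IUPAC_EXPAND[[l]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

#' Plant motif instances in designated promoters
#'
#' Rewrites every promoter from a GC-only alphabet and then plants, for each
#' motif, one concrete instance (a random non-degenerate expansion of the
#' consensus) in each designated carrier promoter, at a random position, in
#' the gene's promoter orientation. Because every instance is isolated in a
#' G/C background, rescanning recovers exactly the designated carrier sets
#' for any motif whose every expansion contains an A or a T (true of all six
#' catalogue motifs); a warning is issued for motifs that can match a GC-only
#' sequence.
#'
#' @param genome named `DNAStringSet`.
#' @param annotation gene table as from [sim_annotation()].
#' @param catalog data.frame with columns `motif_id`, `iupac`.
#' @param carriers named list: `motif_id` -> character vector of carrier
#'   gene ids.
#' @param promoter_length promoter length in bp (default 1000).
#' @param seed optional integer seed.
#' @return List with `genome` (modified) and `carriers` (the ground-truth
#'   carrier sets, as given).
#' @export
plant_motifs <- function(genome, annotation, catalog, carriers,
                         promoter_length = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(names(carriers) %in% catalog$motif_id))
    stop("carriers refer to motifs absent from the catalog")
  for (m in catalog$iupac) {
    motif <- check_iupac(m)
    if (nchar(motif) > promoter_length)
      stop("motif longer than the promoter: ", motif)
    gc_ok <- all(vapply(strsplit(motif, "")[[1]], function(l)
      any(IUPAC_EXPAND[[l]] %in% c("G", "C")), logical(1)))
    if (gc_ok)
      warning("motif ", motif, " can match a GC-only background; ",
              "planted carrier sets will not be exact for it")
  }
  bad <- setdiff(unlist(carriers), annotation$gene_id)
  if (length(bad))
    stop("carrier gene(s) not annotated: ", paste(utils::head(bad, 5),
                                                  collapse = ", "))
  iupac_of <- stats::setNames(catalog$iupac, catalog$motif_id)
  ## per-gene list of motifs to plant
  per_gene <- split(rep(names(carriers), lengths(carriers)),
                    unlist(carriers))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  ng <- nrow(annotation)
  plus <- annotation$strand == "+"
  p_start <- ifelse(plus, annotation$tss - promoter_length, annotation$tss + 1)
  p_end <- ifelse(plus, annotation$tss - 1, annotation$tss + promoter_length)
  if (any(p_start < 1 | p_end > clen[annotation$chrom]))
    stop("promoter(s) exceed the contig for: ",
         paste(annotation$gene_id[p_start < 1 |
                                    p_end > clen[annotation$chrom]],
               collapse = ", "))
  proms <- character(ng)
  for (i in seq_len(ng)) {
    g <- annotation$gene_id[i]
    prom <- sample(c("G", "C"), promoter_length, replace = TRUE)
    occupied <- integer(0)
    for (m in per_gene[[g]]) {
      inst <- strsplit(expand_iupac_once(iupac_of[[m]]), "")[[1]]
      w <- length(inst)
      repeat {  # keep instances separated by >= 1 background base
        pos <- sample.int(promoter_length - w + 1, 1)
        if (!any(seq(pos - 1, pos + w) %in% occupied)) break
      }
      prom[pos:(pos + w - 1)] <- inst
      occupied <- c(occupied, seq(pos, pos + w - 1))
    }
    proms[i] <- paste(prom, collapse = "")
  }
  repl <- Biostrings::DNAStringSet(proms)
  repl[!plus] <- Biostrings::reverseComplement(repl[!plus])
  out <- genome
  for (ch in unique(annotation$chrom)) {  # one batched edit per contig
    sel <- annotation$chrom == ch
    out[[ch]] <- Biostrings::replaceAt(
      out[[ch]], IRanges::IRanges(p_start[sel], p_end[sel]), repl[sel])
  }
  list(genome = out, carriers = carriers)
}

#' Simulate negative-binomial counts with planted expression effects
#'
#' Per-gene mean counts are proportional to a baseline expression level
#' times a length factor (`exon_length / 1500`), multiplied by
#' `2^effects` in each condition, then scaled so every column's expected
#' sum equals its library size; counts are drawn negative-binomial with a
#' common dispersion. The DE ground truth is defined by the planted
#' effects: versus the first (control) condition, a gene is truly up in a
#' condition when its log2 effect is `>= 1` and truly down when `<= -1`.
#'
#' @param annotation gene table (uses `gene_id`, `exon_length`).
#' @param expression per-gene baseline expression level (mean-count scale,
#'   before length and library scaling); recycled if length 1.
#' @param effects genes x conditions matrix of log2 effects (first column
#'   is the control and should be 0); default all zero, 3 conditions.
#' @param library_sizes named per-condition expected totals (default
#'   `c(M0 = 1e7, M10 = 1e7, M20 = 1e7)`).
#' @param dispersion negative-binomial dispersion (> 0; default 0.05 — low,
#'   as single libraries carry no replicate variance).
#' @param seed optional integer seed.
#' @return List with `counts` (integer matrix, genes x conditions) and
#'   `truth`: `de_up` and `de_down`, each a named list (one gene-id vector
#'   per non-control condition).
#' @export
sim_counts <- function(annotation, expression = 1000, effects = NULL,
                       library_sizes = c(M0 = 1e7, M10 = 1e7, M20 = 1e7),
                       dispersion = 0.05, seed = NULL) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  ng <- nrow(annotation)
  conds <- names(library_sizes)
  if (is.null(effects))
    effects <- matrix(0, ng, length(library_sizes))
  if (!all(dim(effects) == c(ng, length(library_sizes))))
    stop("`effects` must be genes x conditions")
  if (any(!is.finite(effects))) stop("effect sizes must be finite")
  expression <- rep_len(expression, ng)
  mu <- expression * (annotation$exon_length / 1500) * 2^effects
  mu <- sweep(mu, 2, library_sizes / colSums(mu), "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   ng, length(conds),
                   dimnames = list(annotation$gene_id, conds))
  storage.mode(counts) <- "integer"
  de_up <- de_dn <- list()
  for (j in seq_along(conds)[-1]) {
    de_up[[conds[j]]] <- annotation$gene_id[effects[, j] >= 1]
    de_dn[[conds[j]]] <- annotation$gene_id[effects[, j] <= -1]
  }
  list(counts = counts, truth = list(de_up = de_up, de_down = de_dn))
}

#' Simulate a qRT-PCR Ct table with known log2 ratios
#'
#' Generates target and reference (ACTIN1) Ct values such that
#' delta-delta-Ct recovers the planted log2 ratios in expectation: the
#' target Ct drops by one cycle per planted doubling. With `noise_sd = 0`
#' the inversion is exact.
#'
#' @param true_log2 genes x conditions matrix of planted log2 ratios versus
#'   the first (control) column, which must be zero; rownames are gene ids.
#' @param noise_sd per-well Ct noise SD in cycles (default 0.2).
#' @param replicates biological replicates per gene x condition (default 3).
#' @param seed optional integer seed.
#' @return data.frame `gene_id`, `condition`, `replicate`, `ct_target`,
#'   `ct_actin`.
#' @export
sim_qpcr <- function(true_log2, noise_sd = 0.2, replicates = 3, seed = NULL) {
  if (replicates < 2) stop("need >= 2 replicates")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  true_log2 <- as.matrix(true_log2)
  if (any(true_log2[, 1] != 0))
    stop("first column of `true_log2` is the control and must be zero")
  genes <- rownames(true_log2)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(true_log2)))
  conds <- colnames(true_log2)
  if (is.null(conds)) conds <- paste0("cond", seq_len(ncol(true_log2)))
  base_ct <- stats::setNames(stats::runif(length(genes), 22, 28), genes)
  grid <- expand.grid(replicate = seq_len(replicates), condition = conds,
                      gene_id = genes, stringsAsFactors = FALSE)
  grid <- grid[, c("gene_id", "condition", "replicate")]
  planted <- true_log2[cbind(grid$gene_id, grid$condition)]
  nwell <- nrow(grid)
  grid$ct_target <- base_ct[grid$gene_id] - planted +
    stats::rnorm(nwell, 0, noise_sd)
  grid$ct_actin <- 18 + stats::rnorm(nwell, 0, noise_sd)
  rownames(grid) <- NULL
  grid
}

#' Simulate root gravitropism tip angles
#'
#' One tip angle per seedling per treatment, normal around the group mean
#' and clipped to the physically meaningful range 0-90 degrees (roots bend
#' back toward gravity after a 90-degree reorientation).
#'
#' @param means named per-treatment mean angles in degrees (defaults follow
#'   the study's reported group means).
#' @param sd common SD in degrees (default 10).
#' @param n seedlings per treatment (default 30).
#' @param seed optional integer seed.
#' @return data.frame `seedling_id`, `treatment`, `angle`.
#' @export
sim_gravitropism <- function(means = c(M0 = 55.9, M10 = 71.9, M20 = 66.5,
                                       M50 = 66.4),
                             sd = 10, n = 30, seed = NULL) {
  if (sd < 0) stop("sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(data.frame(seedling_id = character(), treatment = character(),
                      angle = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(names(means), function(tr) {
    ang <- pmin(pmax(stats::rnorm(n, means[[tr]], sd), 0), 90)
    data.frame(seedling_id = sprintf("%s_s%02d", tr, seq_len(n)),
               treatment = tr, angle = ang, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
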