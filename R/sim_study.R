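#' Expression prototypes for the eight planted co-expression clusters
#'
#' After per-gene log2/z-score normalisation every 3-sample profile lies on
#' a circle (the unit sphere of the mean-zero plane), so cluster prototypes
#' are parameterised as equally spaced directions on that circle. The
#' returned matrix gives each prototype's log2 effects relative to the
#' control condition (first column, all zero). With the default offset the
#' per-comparison planted effects stay clear of the 2-fold calling
#' boundary: every effect is either at least 2.15 or at most 0.46 in
#' absolute log2 units.
#'
#' Exactly two prototypes are up in both treatments ("co-up" patterns) and
#' two are down in both ("co-down"); the remainder respond in a single
#' treatment or in opposite directions, mirroring the cluster structure
#' reported for melatonin-treated roots.
#'
#' @param amplitude log2 amplitude of the prototypes (default 2.5).
#' @param offset angular offset of the prototype grid in radians (default
#'   `pi / 8`).
#' @param n_conditions number of conditions (currently 3).
#' @return 8 x `n_conditions` matrix of log2 effects, control column zero.
#' @export
cluster_prototypes <- function(amplitude = 2.5, offset = pi / 8,
                               n_conditions = 3) {
  if (n_conditions != 3)
    stop("prototypes are defined for the 3-condition design")
  u1 <- c(-2, 1, 1) / sqrt(6)
  u2 <- c(0, 1, -1) / sqrt(2)
  th <- offset + (0:7) * pi / 4
  v <- cbind(cos(th)) %*% rbind(u1) + cbind(sin(th)) %*% rbind(u2)
  eff <- amplitude * v
  eff <- eff - eff[, 1]  # express relative to the control condition
  dimnames(eff) <- list(paste0("K", 1:8), c("M0", "M10", "M20"))
  eff
}

#' The six-motif cis-element catalogue used by the study
#'
#' Reads the packaged catalogue (ARF binding site TGTCTC, auxin response
#' element TACACAT, root tip meristem element TATTCT, root-specific element
#' ATATT, and the two W-box cores TTGAC / TGACT) from `inst/extdata`.
#'
#' @return data.frame with columns `motif_id`, `iupac`, `name`.
#' @export
study_motif_catalog <- function() {
  utils::read.delim(system.file("extdata", "motif_catalog.tsv",
                                package = "melroot"),
                    stringsAsFactors = FALSE)
}

default_motif_catalog <- function() {
  data.frame(
    motif_id = paste0("motif", 1:6),
    iupac = c("TGTCTC", "TACACAT", "TATTCT", "ATATT", "TTGAC", "TGACT"),
    name = c("ARF binding site", "auxin response element",
             "root tip meristem element", "root-specific element (RSE)",
             "W-box (TTGAC)", "W-box (TGACT)"),
    stringsAsFactors = FALSE)
}

TF_FAMILIES <- c("WRKY", "NAC", "MYB", "bHLH", "LBD", "C3H", "HD-ZIP", "SRS",
                 "B3", "HSF", "DBB", "C2H2", "ARF", "ERF", "TCP", "MIKC",
                 "GRF", "DOF", "bZIP", "GATA", "MADS", "AP2", "SBP",
                 "Trihelix")

#' Simulate a complete melatonin-root study with recorded ground truth
#'
#' Generates every input the analysis pipeline consumes — genome, gene
#' models, promoters with planted cis-element carriers, three single-library
#' count columns (M0/M10/M20) with planted differential expression and
#' cluster structure, GO and TF-family annotation tables, a qRT-PCR Ct table
#' and a gravitropism angle table — together with the ground truth needed
#' for recovery testing.
#'
#' The default configuration emulates the study's printed headline
#' structure: 314 genes up-regulated in both treatments and 51 down in
#' both (split across the two both-up and two both-down prototypes of
#' [cluster_prototypes()]), six further co-expression classes, and
#' promoter-motif carriers at the printed counts (e.g. the root-specific
#' element in 46 of the 51 co-down genes, TACACAT in 9 of 51, and the
#' ARF-site/meristem-element/RSE in 79/95/266 of the 314 co-up genes; the
#' two W-box variants, for which no count is printed, are planted in
#' 130 and 110 co-up promoters). Null genes span a wide expression range so
#' that the planted differential-expression mass stays small relative to
#' the library — single-library FPKM fold changes are sensitive to library
#' composition.
#'
#' @param n_genes gene universe size (default 2000).
#' @param cluster_sizes integer vector of 8 prototype class sizes; the
#'   default plants 314 co-up (254 + 60) and 51 co-down (26 + 25) genes.
#' @param amplitude prototype log2 amplitude (default 2.5).
#' @param motif_carriers `"printed"` (default) for the printed-count
#'   emulation, or `list(fraction =, background =)` to plant every
#'   catalogue motif in a fraction of the co-up genes against a genome-wide
#'   background carrier rate.
#' @param library_sizes,dispersion see [sim_counts()].
#' @param promoter_length promoter length in bp (default 1000).
#' @param qpcr_genes genes sampled (from the planted DE classes) for the
#'   qRT-PCR table (default 36).
#' @param qpcr_noise_sd per-well Ct noise SD (default 0.2).
#' @param gravi_means,gravi_sd,gravi_n see [sim_gravitropism()].
#' @param seed integer seed; the whole study is reproducible from it.
#' @return A `sim_study` list: `genome`, `annotation`, `counts`, `catalog`,
#'   `go_map`, `tf_map`, `qpcr`, `qpcr_truth`, `gravitropism`,
#'   `library_sizes`, `promoter_length`, and `truth` (a list with `de_up`,
#'   `de_down`, `co_up`, `co_down`, `cluster_labels`, `motif_carriers`,
#'   `enriched_go`).
#' @export
sim_study <- function(n_genes = 2000,
                      cluster_sizes = c(254, 60, 60, 26, 25, 60, 60, 60),
                      amplitude = 2.5,
                      motif_carriers = "printed",
                      library_sizes = c(M0 = 1e7, M10 = 1e7, M20 = 1e7),
                      dispersion = 0.05,
                      promoter_length = 1000,
                      qpcr_genes = 36, qpcr_noise_sd = 0.2,
                      gravi_means = c(M0 = 55.9, M10 = 71.9, M20 = 66.5,
                                      M50 = 66.4),
                      gravi_sd = 10, gravi_n = 30,
                      seed = NULL) {
  if (length(cluster_sizes) != 8) stop("need 8 cluster class sizes")
  if (sum(cluster_sizes) > n_genes)
    stop("cluster classes exceed the gene universe")
  if (!is.null(seed)) set.seed(seed)

  geno <- sim_annotation(n_genes, promoter_length = promoter_length)
  ann <- geno$annotation
  genes <- ann$gene_id

  ## --- planted cluster / DE structure ------------------------------------
  proto <- cluster_prototypes(amplitude)
  cl_genes <- sample(genes, sum(cluster_sizes))
  labels <- stats::setNames(rep(seq_len(8), cluster_sizes), cl_genes)
  eff <- matrix(0, n_genes, 3, dimnames = list(genes, colnames(proto)))
  eff[cl_genes, ] <- proto[labels, ]
  both_up <- rownames(proto)[proto[, "M10"] >= 1 & proto[, "M20"] >= 1]
  both_dn <- rownames(proto)[proto[, "M10"] <= -1 & proto[, "M20"] <= -1]
  co_up <- cl_genes[labels %in% match(both_up, rownames(proto))]
  co_down <- cl_genes[labels %in% match(both_dn, rownames(proto))]

  ## DE genes at moderate expression (mean counts >= 500), null genes over a
  ## wide range so the planted DE mass is a small library fraction
  expression <- numeric(n_genes)
  is_cl <- genes %in% cl_genes
  expression[is_cl] <- exp(stats::runif(sum(is_cl), log(625), log(1000)))
  expression[!is_cl] <- exp(stats::runif(sum(!is_cl), log(625), log(5e4)))

  cnt <- sim_counts(ann, expression = expression, effects = eff,
                    library_sizes = library_sizes, dispersion = dispersion)

  ## --- promoter motif carriers -------------------------------------------
  catalog <- default_motif_catalog()
  others <- function(excl) setdiff(genes, excl)
  pick <- function(pool, k) sample(pool, min(k, length(pool)))
  if (identical(motif_carriers, "printed")) {
    focal <- list(motif1 = list(set = co_up, k = 79),
                  motif2 = list(set = co_down, k = 9),
                  motif3 = list(set = co_up, k = 95),
                  motif5 = list(set = co_up, k = 130),
                  motif6 = list(set = co_up, k = 110))
    carriers <- lapply(focal, function(f)
      c(pick(f$set, f$k), pick(others(f$set), round(0.05 * length(others(f$set))))))
    ## the RSE is planted in both co-regulated sets
    rse_focal <- c(pick(co_up, 266), pick(co_down, 46))
    carriers$motif4 <- c(rse_focal,
                         pick(others(c(co_up, co_down)),
                              round(0.05 * length(others(c(co_up, co_down))))))
    carriers <- carriers[catalog$motif_id]
  } else {
    fr <- motif_carriers$fraction
    bg <- motif_carriers$background
    carriers <- lapply(catalog$motif_id, function(m)
      c(pick(co_up, round(fr * length(co_up))),
        pick(others(co_up), round(bg * length(others(co_up))))))
    names(carriers) <- catalog$motif_id
  }
  planted <- plant_motifs(geno$genome, ann, catalog, carriers,
                          promoter_length = promoter_length)

  ## --- GO annotation with planted enriched terms -------------------------
  filler_terms <- sprintf("GO:%07d", 1:30)
  n_fill <- sample(1:4, n_genes, replace = TRUE)
  go_map <- data.frame(
    gene_id = rep(genes, n_fill),
    go_id = unlist(lapply(n_fill, function(k) sample(filler_terms, k))),
    stringsAsFactors = FALSE)
  planted_go <- data.frame(
    go_id = c("GO:0009733", "GO:0009734", "GO:0006950", "GO:0048364"),
    name = c("response to auxin", "auxin-activated signaling pathway",
             "response to stress", "root development"),
    gene_set = c("co_up", "co_up", "co_up", "co_down"),
    focal_fraction = c(0.35, 0.25, 0.40, 0.30),
    background_fraction = c(0.03, 0.02, 0.08, 0.03),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(planted_go))) {
    set <- if (planted_go$gene_set[i] == "co_up") co_up else co_down
    hit <- c(pick(set, round(planted_go$focal_fraction[i] * length(set))),
             pick(others(set),
                  round(planted_go$background_fraction[i] *
                          length(others(set)))))
    go_map <- rbind(go_map, data.frame(gene_id = hit,
                                       go_id = planted_go$go_id[i],
                                       stringsAsFactors = FALSE))
  }
  go_map <- unique(go_map)

  ## --- TF-family table ----------------------------------------------------
  single_cond <- setdiff(cl_genes, c(co_up, co_down))
  tf_genes <- c(pick(co_up, 30), pick(co_down, 14), pick(single_cond, 76))
  fam_w <- c(6, rep(2, 7), rep(1, 16))  # WRKY the most common family
  tf_map <- data.frame(
    gene_id = tf_genes,
    family = sample(TF_FAMILIES, length(tf_genes), replace = TRUE,
                    prob = fam_w / sum(fam_w)),
    stringsAsFactors = FALSE)

  ## --- validation tables --------------------------------------------------
  qp_genes <- pick(cl_genes, qpcr_genes)
  qpcr_truth <- eff[qp_genes, , drop = FALSE]
  qpcr <- sim_qpcr(qpcr_truth, noise_sd = qpcr_noise_sd)
  gravi <- sim_gravitropism(gravi_means, sd = gravi_sd, n = gravi_n)

  structure(list(
    genome = planted$genome, annotation = ann, counts = cnt$counts,
    catalog = catalog, go_map = go_map, tf_map = tf_map,
    qpcr = qpcr, qpcr_truth = qpcr_truth, gravitropism = gravi,
    library_sizes = library_sizes, promoter_length = promoter_length,
    truth = list(de_up = cnt$truth$de_up, de_down = cnt$truth$de_down,
                 co_up = co_up, co_down = co_down,
                 cluster_labels = labels,
                 motif_carriers = planted$carriers,
                 enriched_go = planted_go)),
    class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic melatonin-root study:\n")
  cat("  genes:", nrow(x$annotation),
      " | genome:", sum(Biostrings::width(x$genome)), "bp\n")
  cat("  planted co-up:", length(x$truth$co_up),
      " co-down:", length(x$truth$co_down),
      " clustered:", length(x$truth$cluster_labels), "\n")
  invisible(x)
}
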