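#' Run the full melatonin-root analysis pipeline
#'
#' Executes every analysis stage on a study (typically a [sim_study()]
#' object, or any list carrying the same elements): FPKM quantification,
#' fold-change DEG calling for M10 and M20 against the M0 control, the
#' co-up/co-down intersections, silhouette-selected K-means clustering of
#' the normalised DEG profiles, promoter extraction and motif-carrier
#' enrichment, GO over-representation of the co-regulated sets, the
#' TF-family cross-tabulation, qRT-PCR relative quantification with the
#' RNA-seq concordance regression, and gravitropism angle statistics.
#'
#' @param study list with `counts`, `annotation`, `genome`, `catalog`,
#'   `go_map`, `tf_map`, `qpcr`, `gravitropism`, `promoter_length`.
#' @param fold,pseudocount,min_fpkm DEG-calling parameters (see
#'   [call_degs()]).
#' @param totals optional per-library total mapped reads override for FPKM.
#' @param k_range candidate cluster numbers (default 2:12).
#' @param n_init K-means restarts (default 10).
#' @param alpha significance level for enrichment (default 0.05, raw
#'   p-values as in the original analysis).
#' @param seed seed for the clustering stage.
#' @return A list with elements `expr`, `degs` (per treatment), `overlap`,
#'   `normalized`, `k_selection`, `clusters`, `promoters`, `carriers`,
#'   `motif_enrichment`, `go_enrichment` (per co-set), `tf`, `qpcr`,
#'   `concordance`, `gravi`.
#' @export
run_pipeline <- function(study, fold = 2, pseudocount = 1, min_fpkm = 1,
                         totals = NULL, k_range = 2:12, n_init = 10,
                         alpha = 0.05, seed = 1) {
  ann <- study$annotation
  lengths <- stats::setNames(ann$exon_length, ann$gene_id)
  expr <- if (is.null(totals)) compute_fpkm(study$counts, lengths)
          else compute_fpkm(study$counts, lengths, totals)
  control <- colnames(study$counts)[1]
  treatments <- colnames(study$counts)[-1]
  degs <- lapply(treatments, function(tr)
    call_degs(expr, tr, control, fold = fold, pseudocount = pseudocount,
              min_fpkm = min_fpkm))
  names(degs) <- treatments
  overlap <- intersect_degs(degs[[1]], degs[[2]])

  deg_union <- unique(unlist(lapply(degs, function(d)
    c(deg_genes(d, "up"), deg_genes(d, "down")))))
  norm <- normalize_expression(expr$fpkm[deg_union, , drop = FALSE])
  ks <- select_k(norm, k_range = k_range, n_init = n_init, seed = seed)
  cl <- cluster_expression(norm, ks$k, n_init = n_init, seed = seed)

  promoters <- extract_promoters(study$genome, ann,
                                 length = study$promoter_length)
  carriers <- carrier_table(promoters, study$catalog)
  sets <- list(co_up = overlap$co_up, co_down = overlap$co_down)
  me <- motif_enrichment(carriers, sets, alpha = alpha)

  go_ann <- data.frame(gene_id = study$go_map$gene_id,
                       feature_id = study$go_map$go_id,
                       stringsAsFactors = FALSE)
  go <- lapply(sets, enrich_features, universe = ann$gene_id,
               annotation = go_ann, alpha = alpha)

  tf <- tf_crosstab(sets, study$tf_map)

  rel <- relative_expression(study$qpcr, control = control)
  pairs <- rel[rel$condition != control, ]
  rna <- do.call(rbind, lapply(treatments, function(tr) {
    d <- degs[[tr]]
    data.frame(gene_id = d$gene_id, condition = tr, rnaseq = d$log2fc,
               stringsAsFactors = FALSE)
  }))
  pairs <- merge(pairs, rna, by = c("gene_id", "condition"))
  conc <- concordance_regression(pairs$log2_ratio, pairs$rnaseq)

  gr <- study$gravitropism
  gravi <- list(
    bins = bin_angles(gr),
    means = tapply(gr$angle, gr$treatment, mean),
    tests = lapply(setdiff(unique(gr$treatment), control), function(tr)
      group_compare(gr$angle[gr$treatment == tr],
                    gr$angle[gr$treatment == control])))
  names(gravi$tests) <- setdiff(unique(gr$treatment), control)

  list(expr = expr, degs = degs, overlap = overlap, normalized = norm,
       k_selection = ks, clusters = cl, promoters = promoters,
       carriers = carriers, motif_enrichment = me, go_enrichment = go,
       tf = tf, qpcr = rel, concordance = conc, gravi = gravi)
}
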