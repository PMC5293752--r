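#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`: the probability of
#' drawing at least `k` feature-positive genes when `n` genes are drawn
#' without replacement from a universe of `M` genes of which `K` carry the
#' feature. The inclusive upper tail equals the one-sided ("greater")
#' Fisher's exact test on the corresponding 2x2 table, the standard
#' over-representation convention.
#'
#' The tail is accumulated in log space: each probability mass term is
#' evaluated with [lchoose()], terms are shifted by the modal term before
#' exponentiation, and the sum is returned on the requested scale. This keeps
#' relative accuracy for deep tails where naive summation underflows.
#' Vectorised over all four arguments.
#'
#' @param k observed feature-positives in the drawn set.
#' @param n drawn-set size.
#' @param K feature-positives in the universe.
#' @param M universe size.
#' @param log.p return `log(p)` instead of `p`.
#' @return `P(X >= k)`; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_upper(4, 4, 5, 10)  # choose(5,4)/choose(10,4) = 5/210
#' @export
hypergeom_upper <- function(k, n, K, M, log.p = FALSE) {
  len <- max(length(k), length(n), length(K), length(M))
  k <- rep_len(as.numeric(k), len); n <- rep_len(as.numeric(n), len)
  K <- rep_len(as.numeric(K), len); M <- rep_len(as.numeric(M), len)
  if (any(k != floor(k) | n != floor(n) | K != floor(K) | M != floor(M)))
    stop("all counts must be integers")
  if (any(M < 0 | K < 0 | n < 0 | k < 0))
    stop("all counts must be non-negative")
  if (any(n > M) || any(K > M))
    stop("inconsistent counts: need n <= M and K <= M")
  lo <- pmax(0, n + K - M)
  hi <- pmin(n, K)
  if (any(k > hi) || any(k < lo))
    stop("inconsistent counts: need max(0, n + K - M) <= k <= min(n, K)")

  nterm <- hi - k + 1
  id <- rep.int(seq_len(len), nterm)
  i <- sequence(nterm) - 1 + rep.int(k, nterm)
  lpmf <- lchoose(K[id], i) + lchoose(M[id] - K[id], n[id] - i) -
    lchoose(M[id], n[id])
  ## shift by the largest term: the pmf mode, clamped into [k, hi]
  s <- pmin(pmax(k, floor((n + 1) * (K + 1) / (M + 2))), hi)
  lmax <- lchoose(K, s) + lchoose(M - K, n - s) - lchoose(M, n)
  tot <- rowsum(exp(lpmf - lmax[id]), id, reorder = TRUE)
  lp <- pmin(lmax + log(as.vector(tot)), 0)
  if (log.p) lp else exp(lp)
}

#' Feature over-representation in a gene set
#'
#' Tests every feature (GO term, motif, gene family, ...) annotated to at
#' least one query gene for over-representation relative to a gene universe,
#' using the inclusive upper-tail hypergeometric test
#' ([hypergeom_upper()]). Raw p-values are compared against `alpha` by
#' default, mirroring the original analysis; Benjamini-Hochberg adjustment is
#' available (and advisable) via `adjust = "BH"`, in which case significance
#' is assessed on the adjusted values.
#'
#' @param query character vector of query gene ids (subset of `universe`).
#' @param universe character vector: the background gene universe.
#' @param annotation data.frame with columns `gene_id` and `feature_id`
#'   (one row per gene-feature link); links to genes outside `universe` are
#'   ignored.
#' @param alpha significance level (default 0.05).
#' @param adjust multiple-testing correction, `"none"` (default) or any
#'   method of [stats::p.adjust()].
#' @return An `enrichment` data.frame sorted by p-value with columns
#'   `feature_id`, `k`, `n`, `K`, `M`, `fold`, `p`, `p_adj`, `significant`.
#' @export
enrich_features <- function(query, universe, annotation, alpha = 0.05,
                            adjust = "none") {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop("query genes absent from universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  if (!all(c("gene_id", "feature_id") %in% names(annotation)))
    stop("`annotation` needs columns gene_id and feature_id")
  ann <- unique(annotation[annotation$gene_id %in% universe,
                           c("gene_id", "feature_id")])
  M <- length(universe)
  n <- length(query)
  Ktab <- table(ann$feature_id)
  inq <- ann[ann$gene_id %in% query, ]
  ktab <- table(inq$feature_id)
  feats <- names(ktab)  # only features hit at least once in the query
  k <- as.integer(ktab[feats])
  K <- as.integer(Ktab[feats])
  p <- if (length(feats)) hypergeom_upper(k, n, K, M) else numeric(0)
  p_adj <- stats::p.adjust(p, method = adjust)
  out <- data.frame(feature_id = feats, k = k, n = n, K = K, M = M,
                    fold = (k / n) / (K / M), p = p, p_adj = p_adj,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- if (adjust == "none") out$p < alpha else out$p_adj < alpha
  out <- out[order(out$p, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment", "data.frame"),
            alpha = alpha, adjust = adjust)
}

#' @export
print.enrichment <- function(x, ...) {
  cat("Enrichment:", nrow(x), "features tested, ",
      sum(x$significant), "significant (alpha ", attr(x, "alpha"),
      ", adjust ", attr(x, "adjust"), ")\n", sep = "")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Motif-carrier enrichment in DEG sets
#'
#' For every motif and every DEG set, tests whether promoters carrying the
#' motif are over-represented in the set relative to a background of
#' annotated genes: `M` background genes of which `K` carry the motif,
#' against `k` carriers among the `n` set genes. Carrier status is
#' presence/absence, not occurrence count. The carrier percentage of each
#' set is reported through [fraction_report()].
#'
#' @param carriers logical gene x motif matrix from [carrier_table()].
#' @param gene_sets named list of character vectors (e.g. co-up / co-down
#'   DEG ids); every gene must appear in `carriers`.
#' @param background character vector of background gene ids (default: all
#'   rows of `carriers`, i.e. all annotated genes).
#' @param alpha,adjust see [enrich_features()].
#' @return An `enrichment` data.frame with one row per motif x set, columns
#'   `feature_id`, `gene_set`, `k`, `n`, `K`, `M`, `carrier_pct`, `fold`,
#'   `p`, `p_adj`, `significant`.
#' @export
motif_enrichment <- function(carriers, gene_sets, background = rownames(carriers),
                             alpha = 0.05, adjust = "none") {
  carriers <- as.matrix(carriers)
  if (!all(background %in% rownames(carriers)))
    stop("carrier table does not cover the background")
  missing <- lapply(gene_sets, setdiff, y = rownames(carriers))
  bad <- vapply(missing, length, 1L) > 0
  if (any(bad))
    stop("DEG genes absent from carrier table: ",
         paste(utils::head(unlist(missing), 5), collapse = ", "))
  bg <- carriers[background, , drop = FALSE]
  M <- length(background)
  rows <- list()
  for (set in names(gene_sets)) {
    genes <- gene_sets[[set]]
    n <- length(genes)
    for (m in colnames(carriers)) {
      K <- sum(bg[, m])
      k <- sum(carriers[genes, m])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = m, gene_set = set, k = k, n = n, K = K, M = M,
        carrier_pct = if (n > 0) fraction_report(k, n) else NA_real_,
        fold = if (n > 0 && K > 0) (k / n) / (K / M) else NA_real_,
        p = hypergeom_upper(k, n, K, M), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- if (adjust == "none") out$p < alpha else out$p_adj < alpha
  out <- out[order(out$gene_set, out$p), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment", "data.frame"),
            alpha = alpha, adjust = adjust)
}

#' Cross-tabulate transcription-factor families over DEG sets
#'
#' Plain set-join of DEG sets against a user-supplied gene-to-family table,
#' reporting per-set family counts and the share of all listed TFs that each
#' set captures (via [fraction_report()]).
#'
#' @param gene_sets named list of gene-id vectors (e.g. `co_up`, `co_down`).
#' @param tf_map data.frame with columns `gene_id`, `family`.
#' @return List with `families` (family x set count table), `totals`
#'   (TFs per set), `pct` (percentage of all TFs per set) and `n_tf`.
#' @export
tf_crosstab <- function(gene_sets, tf_map) {
  if (!all(c("gene_id", "family") %in% names(tf_map)))
    stop("`tf_map` needs columns gene_id and family")
  tf_map <- unique(tf_map[, c("gene_id", "family")])
  n_tf <- length(unique(tf_map$gene_id))
  if (n_tf == 0) stop("empty TF map")
  fam <- sort(unique(tf_map$family))
  tab <- sapply(gene_sets, function(g) {
    hit <- tf_map[tf_map$gene_id %in% g, ]
    table(factor(hit$family, levels = fam))
  })
  tab <- matrix(tab, nrow = length(fam),
                dimnames = list(fam, names(gene_sets)))
  totals <- vapply(gene_sets, function(g)
    length(intersect(g, tf_map$gene_id)), 1L)
  list(families = tab, totals = totals,
       pct = fraction_report(totals, n_tf), n_tf = n_tf)
}
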