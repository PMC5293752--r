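#' Normalise expression profiles for clustering
#'
#' Per-gene transform of raw FPKM profiles prior to K-means: a pseudocount
#' is added, values are log2-transformed, and each row is z-scored,
#' `V' = (w - mean(w)) / sd(w)` with `w = log2(V + pseudocount)` and the
#' sample (n - 1) standard deviation, so every non-constant row has mean 0
#' and sd 1. Constant rows cannot be scaled and map to all-zero vectors with
#' a warning.
#'
#' `method = "rowsum"` divides the log-profile by its row sum instead of
#' z-scoring; it is kept only for sensitivity checks against the z-score
#' normalisation and is not used elsewhere in the pipeline.
#'
#' @param x numeric matrix of raw FPKM values, genes x samples (>= 2 samples).
#' @param pseudocount value added before the log (default 1).
#' @param method `"zscore"` (default) or `"rowsum"`.
#' @return Matrix of the same dimensions.
#' @examples
#' normalize_expression(matrix(c(1, 3, 7), 1))  # (-1, 0, 1)
#' @export
normalize_expression <- function(x, pseudocount = 1,
                                 method = c("zscore", "rowsum")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 samples to normalise a profile")
  if (any(x < 0)) stop("FPKM values must be non-negative")
  w <- log2(x + pseudocount)
  if (method == "rowsum") {
    s <- rowSums(w)
    return(w / ifelse(s == 0, 1, s))
  }
  mu <- rowMeans(w)
  sdv <- apply(w, 1, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat))
    warning(sum(flat), " constant profile(s) mapped to zero vectors")
  sdv[flat] <- 1
  out <- (w - mu) / sdv
  out[flat, ] <- 0
  out
}

## Lloyd's K-means, best of `nstart` random initialisations. Individual
## restarts can leave a centre empty on tightly separated data; kmeans()
## warns but the multi-start selection makes those runs harmless, so that
## specific warning is muffled.
kmeans_lloyd <- function(x, k, nstart) {
  withCallingHandlers(
    stats::kmeans(x, centers = k, nstart = nstart,
                  algorithm = "Lloyd", iter.max = 100),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Select the number of clusters by mean silhouette width
#'
#' Runs K-means (Lloyd's algorithm, `n_init` random restarts) for every K in
#' `k_range` and returns the K maximising the mean silhouette width under
#' Euclidean distance. Ties break to the smallest K.
#'
#' @param x normalised expression matrix (genes x samples).
#' @param k_range candidate numbers of clusters (default 2:12).
#' @param n_init random restarts per K (default 10).
#' @param seed optional integer seed making the search reproducible.
#' @return A `k_selection` list: `k` (the chosen K) and `summary`, a
#'   data.frame of `k` and `mean_silhouette`.
#' @export
select_k <- function(x, k_range = 2:12, n_init = 10, seed = NULL) {
  x <- as.matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop("k_range must be >= 2")
  if (nrow(x) < max(k_range) + 1)
    stop("need at least max(k_range) + 1 rows")
  if (nrow(unique(x)) == 1)
    stop("degenerate matrix: all rows are identical")
  if (!is.null(seed)) set.seed(seed)
  d <- stats::dist(x)
  ms <- vapply(k_range, function(k) {
    km <- kmeans_lloyd(x, k, n_init)
    mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }, numeric(1))
  best <- k_range[which.max(ms)]  # which.max takes the first (smallest) tie
  structure(list(k = best,
                 summary = data.frame(k = k_range, mean_silhouette = ms)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Silhouette K selection: best K =", x$k, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' K-means clustering of expression profiles
#'
#' Best-of-`n_init` Lloyd's K-means on normalised profiles, with per-gene
#' silhouette widths under Euclidean distance.
#'
#' @param x normalised expression matrix (genes x samples), rownames = gene
#'   ids.
#' @param k number of clusters (>= 2, <= rows).
#' @param n_init random restarts (default 10).
#' @param seed optional integer seed.
#' @return An `expr_clusters` list: `cluster` (named integer vector),
#'   `centers`, `k`, `wcss` (total within-cluster sum of squares),
#'   `silhouette` (named per-gene widths, NA when k equals the number of
#'   rows), `mean_silhouette`, `seed`.
#' @export
cluster_expression <- function(x, k, n_init = 10, seed = NULL) {
  x <- as.matrix(x)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds the number of genes")
  if (!is.null(seed)) set.seed(seed)
  km <- kmeans_lloyd(x, k, n_init)
  sil <- if (k < nrow(x)) {
    sw <- cluster::silhouette(km$cluster, stats::dist(x))[, "sil_width"]
    stats::setNames(sw, rownames(x))
  } else stats::setNames(rep(NA_real_, nrow(x)), rownames(x))
  structure(list(cluster = stats::setNames(km$cluster, rownames(x)),
                 centers = km$centers, k = k, wcss = km$tot.withinss,
                 silhouette = sil,
                 mean_silhouette = mean(sil), seed = seed),
            class = "expr_clusters")
}

#' @export
print.expr_clusters <- function(x, ...) {
  cat("K-means clustering: K =", x$k, ", WCSS =", format(x$wcss), "\n")
  print(table(cluster = x$cluster))
  if (!is.na(x$mean_silhouette))
    cat("mean silhouette:", round(x$mean_silhouette, 3), "\n")
  invisible(x)
}

#' Coverage of retained clusters
#'
#' Number and percentage (via [fraction_report()]) of clustered genes that
#' fall in a retained subset of clusters.
#'
#' @param model an `expr_clusters` object.
#' @param retained cluster labels to retain.
#' @return List with `count`, `total` and `pct`.
#' @export
cluster_coverage <- function(model, retained) {
  labs <- unique(model$cluster)
  if (!all(retained %in% labs)) stop("retained clusters not present in model")
  count <- sum(model$cluster %in% retained)
  list(count = count, total = length(model$cluster),
       pct = fraction_report(count, length(model$cluster)))
}
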