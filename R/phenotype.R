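#' Relative expression from qRT-PCR Ct values (delta-delta-Ct)
#'
#' For every gene x condition, `dCt = mean(Ct_target) - mean(Ct_reference)`
#' over replicates, the relative level is `2^(-dCt)` (expression relative to
#' the reference gene, here ACTIN1), and the log2 ratio versus the control
#' condition is `-(dCt_cond - dCt_control)`. The SD of the per-replicate
#' `Ct_target - Ct_reference` differences is reported.
#'
#' @param ct data.frame with columns `gene_id`, `condition`, `replicate`,
#'   `ct_target`, `ct_actin` (>= 2 replicates per gene x condition).
#' @param control control condition label (default `"M0"`).
#' @return data.frame with one row per gene x condition: `delta_ct`,
#'   `sd_delta_ct`, `rel_level`, `log2_ratio` (0 for the control itself),
#'   `n_rep`.
#' @export
relative_expression <- function(ct, control = "M0") {
  need <- c("gene_id", "condition", "replicate", "ct_target", "ct_actin")
  if (!all(need %in% names(ct)))
    stop("`ct` needs columns: ", paste(need, collapse = ", "))
  if (!control %in% ct$condition)
    stop("control condition not present: ", control)
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_actin)))
    stop("Ct values must be finite")
  d <- ct$ct_target - ct$ct_actin
  key <- interaction(ct$gene_id, ct$condition, drop = TRUE)
  if (any(tapply(d, key, length) < 2))
    stop("need >= 2 replicates per gene x condition")
  ug <- unique(ct[, c("gene_id", "condition")])
  out <- ug
  out$delta_ct <- mapply(function(g, cond)
    mean(d[ct$gene_id == g & ct$condition == cond]), ug$gene_id, ug$condition)
  out$sd_delta_ct <- mapply(function(g, cond)
    stats::sd(d[ct$gene_id == g & ct$condition == cond]), ug$gene_id, ug$condition)
  out$n_rep <- mapply(function(g, cond)
    sum(ct$gene_id == g & ct$condition == cond), ug$gene_id, ug$condition)
  out$rel_level <- 2^(-out$delta_ct)
  ctrl <- out[out$condition == control, c("gene_id", "delta_ct")]
  names(ctrl)[2] <- "delta_ct_control"
  out <- merge(out, ctrl, by = "gene_id", sort = FALSE)
  out$log2_ratio <- -(out$delta_ct - out$delta_ct_control)
  out$delta_ct_control <- NULL
  rownames(out) <- NULL
  out
}

#' Concordance regression of RNA-seq against qRT-PCR log2 ratios
#'
#' Ordinary least squares of the RNA-seq log2 fold changes (y) on the
#' qRT-PCR log2 ratios (x), the standard check that sequencing-derived fold
#' changes track an independent assay; a slope near 1 and a high Pearson r
#' indicate concordance.
#'
#' @param qpcr numeric vector of qRT-PCR log2 ratios (x axis).
#' @param rnaseq numeric vector of RNA-seq log2 fold changes (y axis).
#' @return List with `slope`, `intercept`, `r` (Pearson), `n`.
#' @export
concordance_regression <- function(qpcr, rnaseq) {
  ok <- is.finite(qpcr) & is.finite(rnaseq)
  x <- qpcr[ok]; y <- rnaseq[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (stats::var(x) == 0) stop("zero variance in qPCR ratios")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), n = length(x))
}

#' Bin root tip angles and report per-treatment percentages
#'
#' Default bins follow the study's reporting: `[0, 30]`, `(30, 60]`,
#' `(60, 90]` (reported as 61-90) and `(90, Inf)`. Percentages are computed
#' per treatment with [fraction_report()].
#'
#' @param angles data.frame with columns `treatment` and `angle` (degrees).
#' @param breaks strictly increasing bin edges (default
#'   `c(0, 30, 60, 90, Inf)`); the first bin includes its lower edge.
#' @param labels bin labels (default `"0-30"`, `"30-60"`, `"61-90"`,
#'   `">90"`).
#' @return Matrix of percentages, bins x treatments; attribute `"counts"`
#'   holds the underlying counts.
#' @export
bin_angles <- function(angles, breaks = c(0, 30, 60, 90, Inf),
                       labels = c("0-30", "30-60", "61-90", ">90")) {
  if (!all(c("treatment", "angle") %in% names(angles)))
    stop("`angles` needs columns treatment and angle")
  if (is.unsorted(breaks, strictly = TRUE))
    stop("bins overlap or are unordered: breaks must strictly increase")
  if (length(labels) != length(breaks) - 1)
    stop("need one label per bin")
  if (any(angles$angle < min(breaks) | angles$angle > max(breaks)))
    stop("angles outside the binning range")
  treatments <- unique(as.character(angles$treatment))
  n_per <- table(factor(angles$treatment, levels = treatments))
  if (length(n_per) == 0 || any(n_per == 0))
    stop("treatment group with no seedlings")
  b <- cut(angles$angle, breaks = breaks, labels = labels,
           include.lowest = TRUE, right = TRUE)
  counts <- table(bin = b, treatment = factor(angles$treatment,
                                              levels = treatments))
  pct <- apply(counts, 2, function(k) fraction_report(k, sum(k)))
  rownames(pct) <- labels
  attr(pct, "counts") <- unclass(counts)
  pct
}

#' Two-group comparison: means, SDs and Student's t-test
#'
#' Reports each group's mean and SD and a two-sided two-sample t-test,
#' pooled-variance (Student) by default as in the original analysis; Welch
#' is available via `var_equal = FALSE`. Significance stars follow the
#' study's convention: `*` for p <= 0.05, `**` for p <= 0.01.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param var_equal pooled variance (default TRUE).
#' @return List with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`, `df`, `p`,
#'   `stars`.
#' @export
group_compare <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    ## degenerate limit: identical constants tie (t = 0); distinct constants
    ## separate perfectly (p -> 0)
    same <- mean(a) == mean(b)
    res <- list(t = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = if (same) 1 else 0)
  } else {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  stars <- if (res$p <= 0.01) "**" else if (res$p <= 0.05) "*" else ""
  c(list(mean_a = mean(a), sd_a = stats::sd(a),
         mean_b = mean(b), sd_b = stats::sd(b)), res, list(stars = stars))
}
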