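#' FPKM quantification from a count matrix
#'
#' Computes fragments per kilobase of exon per million mapped reads for every
#' gene and library: `FPKM = 1e9 * C / (N * L)`, where `C` is the number of
#' fragments assigned to the gene in that library, `N` the library's total
#' mapped reads and `L` the gene's exon length in bp.
#'
#' `totals` defaults to the column sums of `counts`. In a real experiment the
#' total number of reads mapped to the genome can exceed the number assigned
#' to annotated genes, so an explicit override is supported.
#'
#' @param counts integer matrix, genes x samples; rownames are gene ids.
#' @param lengths numeric vector of exon lengths (bp), one per gene, in row
#'   order of `counts` (or named by gene id).
#' @param totals per-sample total mapped reads; defaults to `colSums(counts)`.
#' @return An object of class `expr_matrix`: a list with elements `counts`,
#'   `fpkm` (same dimensions as `counts`), `lengths`, `totals`.
#' @examples
#' m <- matrix(c(10L, 0L), 1, 2, dimnames = list("g1", c("s1", "s2")))
#' compute_fpkm(m, lengths = 1000, totals = c(1e6, 1e6))$fpkm
#' @export
compute_fpkm <- function(counts, lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (!is.null(names(lengths)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("`lengths` must provide one exon length per gene")
  if (any(counts < 0)) stop("counts must be non-negative")
  bad <- which(!is.finite(lengths) | lengths <= 0)
  if (length(bad))
    stop("non-positive exon length for gene(s): ",
         paste(rownames(counts)[bad], collapse = ", "))
  if (length(totals) != ncol(counts))
    stop("`totals` must provide one value per sample")
  badN <- which(!is.finite(totals) | totals <= 0)
  if (length(badN))
    stop("non-positive library total for sample(s): ",
         paste(colnames(counts)[badN], collapse = ", "))
  fpkm <- 1e9 * sweep(counts, 2, totals, "/") / lengths
  structure(list(counts = counts, fpkm = fpkm,
                 lengths = stats::setNames(as.numeric(lengths), rownames(counts)),
                 totals = stats::setNames(as.numeric(totals), colnames(counts))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("FPKM expression matrix:", nrow(x$fpkm), "genes x",
      ncol(x$fpkm), "samples\n")
  cat("library totals:", paste(format(x$totals, big.mark = ","), collapse = ", "),
      "\n")
  invisible(x)
}

#' Call differentially expressed genes by FPKM fold change
#'
#' Single-library designs carry no replicate variance, so differential
#' expression is a plain fold-change rule on FPKM: with pseudocount
#' \eqn{\epsilon}, \eqn{FC = (FPKM_t + \epsilon) / (FPKM_c + \epsilon)}.
#' A gene is called up when `FC >= fold` (the boundary is included: "2-fold
#' or higher"), down when `FC <= 1/fold`. Genes below `min_fpkm` in both
#' compared samples are treated as unexpressed and left uncalled; set
#' `min_fpkm = 0` to disable the prefilter.
#'
#' With `pseudocount = 0` a gene expressed only in the treatment sample has
#' infinite fold change; it is called up and flagged in the `unstable`
#' column (symmetrically for control-only expression).
#'
#' @param expr an `expr_matrix` from [compute_fpkm()], or a plain FPKM matrix.
#' @param treatment,control sample (column) names to compare.
#' @param fold fold-change threshold (default 2).
#' @param pseudocount FPKM pseudocount added to both samples (default 1).
#' @param min_fpkm expressed-gene prefilter: minimum FPKM required in at
#'   least one of the two samples (default 1).
#' @return A `deg_set`: a data.frame with columns `gene_id`,
#'   `fpkm_treatment`, `fpkm_control`, `log2fc`, `direction`
#'   (`up`/`down`/`none`), `expressed`, `unstable`; the comparison label and
#'   parameters are stored as attributes.
#' @export
call_degs <- function(expr, treatment, control, fold = 2, pseudocount = 1,
                      min_fpkm = 1) {
  fpkm <- if (inherits(expr, "expr_matrix")) expr$fpkm else as.matrix(expr)
  for (s in c(treatment, control))
    if (!s %in% colnames(fpkm)) stop("sample not found: ", s)
  if (fold <= 1) stop("`fold` must exceed 1")
  if (pseudocount < 0) stop("`pseudocount` must be >= 0")
  ft <- fpkm[, treatment]
  fc <- fpkm[, control]
  expressed <- pmax(ft, fc) >= min_fpkm
  ratio <- (ft + pseudocount) / (fc + pseudocount)
  log2fc <- log2(ratio)
  direction <- rep("none", length(ratio))
  direction[expressed & ratio >= fold] <- "up"
  direction[expressed & ratio <= 1 / fold] <- "down"
  unstable <- expressed & !is.finite(log2fc) |
    (pseudocount == 0 & expressed & (ft == 0 | fc == 0))
  out <- data.frame(gene_id = rownames(fpkm),
                    fpkm_treatment = unname(ft), fpkm_control = unname(fc),
                    log2fc = unname(log2fc),
                    direction = factor(direction, c("up", "down", "none")),
                    expressed = unname(expressed), unstable = unname(unstable),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("deg_set", "data.frame"),
            comparison = paste0(control, "-vs-", treatment),
            treatment = treatment, control = control,
            fold = fold, pseudocount = pseudocount, min_fpkm = min_fpkm)
}

#' @export
print.deg_set <- function(x, ...) {
  tab <- table(x$direction)
  cat("DEG call ", attr(x, "comparison"),
      " (fold >= ", attr(x, "fold"),
      ", pseudocount ", attr(x, "pseudocount"), "):\n", sep = "")
  cat("  up:", tab[["up"]], "  down:", tab[["down"]],
      "  none:", tab[["none"]], "\n")
  invisible(x)
}

#' Extract gene ids from a DEG set
#'
#' @param degs a `deg_set`.
#' @param direction `"up"` or `"down"`.
#' @export
deg_genes <- function(degs, direction = c("up", "down")) {
  direction <- match.arg(direction)
  degs$gene_id[degs$direction == direction]
}

#' Intersect two DEG sets
#'
#' Forms the co-up-regulated and co-down-regulated gene sets shared by two
#' comparisons, along with the comparison-exclusive sets.
#'
#' @param a,b `deg_set` objects over the same gene universe.
#' @return A `deg_overlap` list: `co_up`, `co_down`, `only_a_up`,
#'   `only_b_up`, `only_a_down`, `only_b_down` (character vectors) plus a
#'   `counts` summary.
#' @export
intersect_degs <- function(a, b) {
  if (!setequal(a$gene_id, b$gene_id))
    stop("DEG sets must share the same gene universe")
  ua <- deg_genes(a, "up");   ub <- deg_genes(b, "up")
  da <- deg_genes(a, "down"); db <- deg_genes(b, "down")
  out <- list(co_up = intersect(ua, ub), co_down = intersect(da, db),
              only_a_up = setdiff(ua, ub), only_b_up = setdiff(ub, ua),
              only_a_down = setdiff(da, db), only_b_down = setdiff(db, da))
  out$counts <- vapply(out, length, 1L)
  out$comparisons <- c(a = attr(a, "comparison"), b = attr(b, "comparison"))
  structure(out, class = "deg_overlap")
}

#' @export
print.deg_overlap <- function(x, ...) {
  cat("DEG overlap between", x$comparisons["a"], "and", x$comparisons["b"], "\n")
  cat("  co-up:", x$counts[["co_up"]], "  co-down:", x$counts[["co_down"]], "\n")
  invisible(x)
}

#' Report a count as a percentage, half-up rounded to one decimal
#'
#' Matches the reporting convention of the study tables: `100 * k / n`,
#' rounded half-up to one decimal place (so 14/120 reports as 11.7, not the
#' banker's-rounding 11.6). Vectorised over `k` and `n`.
#'
#' @param k numerator count(s), `0 <= k <= n`.
#' @param n denominator count(s), `n > 0`.
#' @return Numeric percentage(s) with one-decimal resolution.
#' @examples
#' fraction_report(46, 51)  # 90.2
#' @export
fraction_report <- function(k, n) {
  if (any(n <= 0)) stop("`n` must be positive")
  if (any(k < 0 | k > n)) stop("`k` must lie in [0, n]")
  ## integer arithmetic: half-up of 1000*k/n, exact for counts
  floor((2000 * k + n) / (2 * n)) / 10
}
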