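## Independent oracles used across the suite.

## Upper-tail hypergeometric by direct summation of the pmf.
hyper_oracle <- function(k, n, K, M) {
  hi <- min(n, K)
  if (k > hi) stop("invalid k")
  sum(stats::dhyper(k:hi, K, M - K, n))
}

## Brute-force IUPAC matcher: exhaustive shift enumeration with per-letter
## allowed sets; counts overlapping occurrences on the given strand only.
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

brute_count_one_strand <- function(sequence, motif) {
  s <- strsplit(toupper(sequence), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  w <- length(m)
  if (length(s) < w) return(0L)
  hits <- 0L
  for (off in 0:(length(s) - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(s[off + j] %in% iupac_sets[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

brute_count <- function(sequence, motif, both_strands = TRUE) {
  n <- brute_count_one_strand(sequence, motif)
  if (both_strands)
    n <- n + brute_count_one_strand(sequence, revcomp_chr(motif))
  n
}

## Small random study for pipeline-level tests.
tiny_study <- function(seed = 1, n_genes = 300) {
  sim_study(n_genes = n_genes,
            cluster_sizes = c(30, 15, 15, 10, 10, 15, 15, 15),
            qpcr_genes = 12, seed = seed)
}
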