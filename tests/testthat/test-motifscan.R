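toy_genome <- function(seq) {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "chr1"
  g
}

test_that("promoter extraction uses strand-aware coordinate arithmetic", {
  set.seed(31)
  seq <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  g <- toy_genome(seq)
  ann <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(2001, 3000))
  pr <- extract_promoters(g, ann, length = 1000)
  ## + strand, TSS 2001: bases 1001..2000
  expect_equal(as.character(pr$seq[["gp"]]), substr(seq, 1001, 2000))
  expect_equal(unlist(pr$coords[1, c("start", "end")], use.names = FALSE),
               c(1001, 2000))
  ## - strand, TSS 3000: reverse complement of 3001..4000
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seq, 3001, 4000))))
  expect_equal(as.character(pr$seq[["gm"]]), rc)
  expect_false(any(pr$coords$clipped))
})

test_that("promoters are clipped and flagged at contig edges", {
  set.seed(32)
  seq <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  g <- toy_genome(seq)
  ann <- data.frame(gene_id = "gc", chrom = "chr1", strand = "+", tss = 500)
  pr <- extract_promoters(g, ann, length = 1000)
  expect_equal(Biostrings::width(pr$seq)[[1]], 499)
  expect_true(pr$coords$clipped)
  expect_equal(pr$coords$start, 1)  # clipping never goes negative
  bad <- data.frame(gene_id = "gx", chrom = "chrZ", strand = "+", tss = 500)
  expect_error(extract_promoters(g, bad), "chrZ")
})

test_that("BED output abuts the TSS in half-open coordinates", {
  set.seed(33)
  g <- toy_genome(paste(sample(c("A", "C", "G", "T"), 4000, TRUE),
                        collapse = ""))
  ann <- data.frame(gene_id = "gp", chrom = "chr1", strand = "+", tss = 2001)
  pr <- extract_promoters(g, ann)
  bed <- file.path(tempdir(), "prom.bed")
  write_promoter_bed(pr, bed)
  row <- utils::read.delim(bed, header = FALSE)
  expect_equal(row$V2, 1000)          # 0-based start
  expect_equal(row$V3, 2000)          # half-open end == 0-based TSS
  expect_true(row$V2 >= 0)
})

test_that("IUPAC matching agrees with exhaustive shift enumeration", {
  expect_equal(match_iupac("GGATATTGG", "ATATT", both_strands = FALSE)$count, 1)
  expect_true(match_iupac("GGATATTGG", "ATATT")$carrier)
  ## overlapping occurrences: shift enumeration gives hits at offsets 1 and 6
  expect_equal(brute_count("ATATTATATT", "ATATT", both_strands = FALSE), 2)
  expect_equal(match_iupac("ATATTATATT", "ATATT", both_strands = FALSE)$count, 2)
  expect_equal(match_iupac("ATATTATATT", "ATATT")$count,
               brute_count("ATATTATATT", "ATATT"))
  expect_false(match_iupac("GGCCGGCCGG", "ATATT")$carrier)
  ## fully degenerate motif matches every window
  expect_equal(match_iupac("ACGTACGT", "NNNNN", both_strands = FALSE)$count, 4)
  expect_error(match_iupac("ACGT", "AXT"), "invalid IUPAC")
})

test_that("randomised IUPAC matching matches the brute-force oracle", {
  set.seed(17)
  motifs <- c("TGTCTC", "TACACAT", "TATTCT", "ATATT", "TTGAC", "TGACT",
              "WTTSSCGG", "RYN", "TGWCT")
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    m <- sample(motifs, 1)
    for (bs in c(TRUE, FALSE))
      expect_equal(match_iupac(s, m, both_strands = bs)$count,
                   brute_count(s, m, both_strands = bs),
                   info = paste(m, bs, s))
  }
})

test_that("carrier status is reverse-complement invariant", {
  set.seed(19)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    m <- sample(c("ATATT", "TGTCTC", "TGWCT", "RYNAC"), 1)
    rc_s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rc_m <- revcomp_chr(m)
    expect_equal(match_iupac(s, m)$carrier, match_iupac(rc_s, rc_m)$carrier)
  }
})

test_that("carrier_table scans the catalogue and handles degenerate cases", {
  seqs <- Biostrings::DNAStringSet(c(g1 = "GGATATTGGG", g2 = "GGGGCCCCGG",
                                     g3 = "TGTCTCATAT"))
  cat <- data.frame(motif_id = c("rse", "arf"), iupac = c("ATATT", "TGTCTC"))
  ct <- carrier_table(seqs, cat)
  expect_equal(dim(ct), c(3L, 2L))
  expect_equal(unname(colSums(ct)), c(1, 1))
  expect_true(ct["g1", "rse"] && ct["g3", "arf"])
  expect_equal(attr(ct, "counts")["g1", "rse"], 1L)
  empty <- carrier_table(seqs, data.frame(motif_id = character(),
                                          iupac = character()))
  expect_equal(ncol(empty), 0)
  everyN <- carrier_table(seqs, data.frame(motif_id = "n5", iupac = "NNNNN"))
  expect_true(all(everyN))
})
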