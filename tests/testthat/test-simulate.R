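test_that("simulated gene models are non-overlapping with clear upstream", {
  sim <- sim_annotation(10, chrom_length = 100000, seed = 5)
  ann <- sim$annotation
  expect_equal(nrow(ann), 10)
  expect_true(all(ann$end >= ann$start))
  o <- order(ann$start)
  expect_true(all(ann$start[o][-1] > ann$end[o][-10]))  # no overlap
  up_start <- ifelse(ann$strand == "+", ann$tss - 1000, ann$tss + 1)
  up_end <- ifelse(ann$strand == "+", ann$tss - 1, ann$tss + 1000)
  expect_true(all(up_start >= 1))
  expect_true(all(up_end <= Biostrings::width(sim$genome)[1]))
  for (i in 1:10) {  # upstream window hits no gene body
    hit <- ann$start <= up_end[i] & ann$end >= up_start[i]
    expect_false(any(hit))
  }
})

test_that("annotation generator handles empty and infeasible requests", {
  sim0 <- sim_annotation(0, seed = 1)
  expect_equal(nrow(sim0$annotation), 0)
  expect_gt(Biostrings::width(sim0$genome)[1], 0)
  expect_error(sim_annotation(100, chrom_length = 10000), "infeasible")
})

test_that("identical seeds reproduce byte-identical FASTA and GFF3", {
  a <- sim_annotation(5, seed = 77)
  b <- sim_annotation(5, seed = 77)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  write_genome_fasta(a$genome, file.path(d1, "g.fasta"))
  write_genome_fasta(b$genome, file.path(d2, "g.fasta"))
  write_annotation_gff3(a$annotation, file.path(d1, "a.gff3"))
  write_annotation_gff3(b$annotation, file.path(d2, "a.gff3"))
  expect_identical(readLines(file.path(d1, "g.fasta")),
                   readLines(file.path(d2, "g.fasta")))
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d2, "a.gff3")))
})

test_that("planted motif carriers are recovered exactly by rescanning", {
  sim <- sim_annotation(51, seed = 41)
  cat <- data.frame(motif_id = c("rse", "aux"), iupac = c("ATATT", "TACACAT"))
  carriers <- list(rse = sim$annotation$gene_id[1:46],
                   aux = sim$annotation$gene_id[10:18])
  pl <- plant_motifs(sim$genome, sim$annotation, cat, carriers, seed = 42)
  pr <- extract_promoters(pl$genome, sim$annotation)
  ct <- carrier_table(pr, cat)
  expect_equal(sum(ct[, "rse"]), 46)   # exactly the designated carriers
  expect_equal(sort(rownames(ct)[ct[, "rse"]]), sort(carriers$rse))
  expect_equal(sort(rownames(ct)[ct[, "aux"]]), sort(carriers$aux))
})

test_that("zero carrier fraction leaves GC-only promoters motif-free", {
  sim <- sim_annotation(8, seed = 43)
  cat <- data.frame(motif_id = "rse", iupac = "ATATT")
  pl <- plant_motifs(sim$genome, sim$annotation, cat,
                     list(rse = character(0)), seed = 1)
  ct <- carrier_table(extract_promoters(pl$genome, sim$annotation), cat)
  expect_equal(sum(ct), 0)
})

test_that("motifs planted in minus-strand promoters are found strand-aware", {
  sim <- sim_annotation(20, seed = 45)
  minus <- sim$annotation$gene_id[sim$annotation$strand == "-"]
  expect_gt(length(minus), 0)
  cat <- data.frame(motif_id = "aux", iupac = "TACACAT")
  pl <- plant_motifs(sim$genome, sim$annotation, cat,
                     list(aux = minus[1]), seed = 2)
  ct <- carrier_table(extract_promoters(pl$genome, sim$annotation), cat)
  expect_true(ct[minus[1], "aux"])
  expect_equal(sum(ct), 1)
  expect_error(plant_motifs(sim$genome, sim$annotation,
                            data.frame(motif_id = "x",
                                       iupac = strrep("AT", 600)),
                            list(x = minus[1])),
               "longer than the promoter")
})

test_that("counts land near library sizes with planted fold effects", {
  sim <- sim_annotation(200, seed = 51)
  eff <- matrix(0, 200, 3)
  eff[1, 2] <- 2    # 4-fold up in the second condition
  ls <- c(M0 = 2e6, M10 = 2e6, M20 = 2e6)
  cs <- sim_counts(sim$annotation, expression = 3000, effects = eff,
                   library_sizes = ls, seed = 52)
  expect_equal(unname(colSums(cs$counts) / ls), rep(1, 3), tolerance = 0.06)
  expect_equal(cs$truth$de_up$M10, sim$annotation$gene_id[1])
  expect_length(cs$truth$de_down$M10, 0)
  ## Monte-Carlo FPKM ratio for the planted gene, totals overridden so the
  ## planted effect is read off directly
  set.seed(53)
  rat <- replicate(300, {
    cc <- sim_counts(sim$annotation, expression = 3000, effects = eff,
                     library_sizes = ls)$counts
    f <- compute_fpkm(cc, sim$annotation$exon_length, totals = ls)$fpkm
    f[1, "M10"] / f[1, "M0"]
  })
  expect_equal(mean(rat), 4, tolerance = 0.1)
})

test_that("a null simulation yields few fold-change calls at high means", {
  sim <- sim_annotation(800, seed = 55)
  cs <- sim_counts(sim$annotation, expression = 2000, seed = 56)
  f <- compute_fpkm(cs$counts, sim$annotation$exon_length)
  d <- call_degs(f, "M10", "M0")
  expect_lt(mean(d$direction != "none"), 0.05)
  expect_identical(
    sim_counts(sim$annotation, expression = 2000, seed = 56)$counts,
    cs$counts)
  expect_error(sim_counts(sim$annotation, dispersion = 0), "dispersion")
})

test_that("noiseless qPCR tables invert exactly through delta-delta-Ct", {
  tl <- matrix(c(0, 0, 0, 2, -1.5, 0), 3, 2,
               dimnames = list(c("ga", "gb", "gc"), c("M0", "M10")))
  ct <- sim_qpcr(tl, noise_sd = 0, seed = 3)
  rel <- relative_expression(ct, control = "M0")
  m10 <- rel[rel$condition == "M10", ]
  expect_equal(m10$log2_ratio[match(c("ga", "gb", "gc"), m10$gene_id)],
               c(2, -1.5, 0))
  expect_error(sim_qpcr(tl, replicates = 1), "replicates")
})

test_that("gravitropism angles respect the truncation and group design", {
  g0 <- sim_gravitropism(c(M0 = 55.9), sd = 0, n = 5, seed = 1)
  expect_equal(g0$angle, rep(55.9, 5))
  expect_equal(nrow(sim_gravitropism(n = 0)), 0)
  g <- sim_gravitropism(sd = 25, n = 50, seed = 2)
  expect_true(all(g$angle >= 0 & g$angle <= 90))
  expect_equal(unname(table(g$treatment)["M10"]), 50)
})

test_that("the assembled study is self-consistent with its ground truth", {
  st <- tiny_study(seed = 8)
  expect_equal(nrow(st$counts), nrow(st$annotation))
  tr <- st$truth
  expect_true(all(tr$co_up %in% tr$de_up$M10) &&
                all(tr$co_up %in% tr$de_up$M20))
  expect_true(all(tr$co_down %in% tr$de_down$M10) &&
                all(tr$co_down %in% tr$de_down$M20))
  expect_true(all(unlist(tr$motif_carriers) %in% st$annotation$gene_id))
  expect_true(all(names(tr$cluster_labels) %in% st$annotation$gene_id))
  expect_equal(sort(unique(unname(tr$cluster_labels))), 1:8)
  ## printed-count emulation plants up to the printed counts per focal set
  expect_equal(sum(tr$motif_carriers$motif4 %in% tr$co_down),
               min(46, length(tr$co_down)))
  expect_equal(sum(tr$motif_carriers$motif2 %in% tr$co_down),
               min(9, length(tr$co_down)))
})
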