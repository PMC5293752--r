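# melroot

Transcriptomic and phenotypic analysis of melatonin-treated rice roots.

Exogenous melatonin reshapes root architecture in rice, in part through the
auxin pathway. The experiments behind that conclusion have a deliberately
minimal computational core: three RNA-seq libraries (water control M0,
10 µmol M10, 20 µmol M20 melatonin), one library per condition, no
replicates. **melroot** implements that analysis as a tested, reusable R
pipeline for anyone who needs to reproduce it, reuse its pieces, or probe
how it behaves:

* **FPKM quantification** of single-library counts —
  FPKM = 10⁹·C/(N·L) (`compute_fpkm()`);
* **fold-change DEG calling** (FC ≥ 2 up, ≤ ½ down, boundary included,
  pseudocount and expressed-gene prefilter; `call_degs()`), and the
  co-up/co-down intersections between treatments (`intersect_degs()`);
* **profile clustering**: per-gene log₂(x+1) + z-score normalisation
  (`normalize_expression()`), Lloyd's K-means with silhouette-based
  selection of K (`select_k()`, `cluster_expression()`);
* **over-representation testing** for GO terms and promoter cis-elements:
  inclusive upper-tail hypergeometric test, p = P(X ≥ k) for
  X ~ Hypergeom(M, K, n), equal to one-sided Fisher's exact, computed in
  log space (`hypergeom_upper()`, `enrich_features()`,
  `motif_enrichment()`);
* **promoter motif scanning**: strand-aware extraction of the 1000 bp
  upstream of each TSS from FASTA + GFF3, IUPAC-degenerate matching with
  overlaps, carrier (presence/absence) tables (`extract_promoters()`,
  `match_iupac()`, `carrier_table()`); the six-motif study catalogue
  (ARF site TGTCTC, TACACAT, TATTCT, RSE ATATT, W-box TTGAC/TGACT) ships
  in `inst/extdata` (`study_motif_catalog()`);
* **validation statistics**: ΔΔCt relative quantification against ACTIN1
  (`relative_expression()`), RNA-seq/qPCR concordance regression
  (`concordance_regression()`), gravitropism angle binning and Student's
  t group comparisons (`bin_angles()`, `group_compare()`).

Because the original sequencing data were never deposited, the package
also ships a first-class **synthetic-data generator** (`sim_study()`) that
reproduces the study design — genome, annotation, promoters with planted
motif carriers, counts with planted DE/cluster structure, qPCR and
phenotype tables — with full ground truth, so every stage is demonstrably
able to recover what was planted.

## Worked example

```r
library(melroot)

study <- sim_study(seed = 42)   # full synthetic study, printed-count defaults
res   <- run_pipeline(study, seed = 1)

res$overlap
#> DEG overlap between M0-vs-M10 and M0-vs-M20
#>   co-up: 308   co-down: 55

res$k_selection$k
#> [1] 8

subset(as.data.frame(res$motif_enrichment), gene_set == "co_down",
       c(feature_id, k, n, carrier_pct, p))
#>   feature_id  k  n carrier_pct            p
#> 1     motif4 46 55        83.6 4.343252e-25
#> 2     motif2  9 55        16.4 1.922280e-03
#> 3     motif1  9 55        16.4 3.078965e-02
#> 4     motif3  4 55         7.3 7.407460e-01
#> 5     motif6  4 55         7.3 7.971678e-01
#> 6     motif5  2 55         3.6 9.858980e-01

res$concordance[c("slope", "r")]    # RNA-seq vs qPCR log2 ratios
#> $slope  0.864   $r  0.956

round(res$gravi$means, 1)
#>   M0  M10  M20  M50
#> 53.5 73.4 68.6 66.3
```

Reading the output: the generator planted 314 co-up and 51 co-down genes;
the 2-fold rule recovers 308 shared up-calls and 55 shared down-calls (a
handful of composition-driven false positives inflate the down set —
single-library FPKM ratios drift when up-regulation dominates a library).
Silhouette selection finds the eight planted co-expression prototypes. Of
the called co-down genes, 46 carry the root-specific element ATATT
(83.6% of the called set; 46/51 = 90.2% of the planted set) and 9 carry
TACACAT — both strongly over-represented against the 5% genome-wide
background (upper-tail hypergeometric p shown). The qPCR concordance
slope is near 1, and mean root-tip angles per treatment sit near their
planted group means (55.9°, 71.9°, 66.5°, 66.4°).

Every input can also be written to and read from standard formats
(`write_study()`: FASTA, GFF3, TSV, truth JSON; readers
`read_genome_fasta()`, `read_annotation_gff3()`, `read_counts_tsv()`).

## Documentation

`vignettes/melroot-methods.Rmd` describes the model and procedure in
full: the fold-change rule and its guards, the z-score geometry behind
the clustering, the enrichment conventions, what the synthetic generator
does and does not emulate, and the package's numerical choices.
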