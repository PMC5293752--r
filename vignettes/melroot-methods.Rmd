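---
title: "Methods: the melroot analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the melroot analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melroot)
```

melroot re-implements, as tested and composable stages, the computational
analysis used to characterise how exogenous melatonin (10 and 20 µmol
treatments, M10/M20, against a water control M0) reshapes the transcriptome
of rice roots. The experimental design it targets is deliberately austere:
one RNA-seq library per condition, no replicates. Every methodological
choice below follows from that constraint. The package ships a
synthetic-data generator that reproduces the design with recorded ground
truth, so each stage can be demonstrated to recover planted structure; what
this does and does not certify about real data is discussed at the end.

## Quantification and DEG calling

Expression is quantified as fragments per kilobase of exon per million
mapped reads,

$$\mathrm{FPKM} = \frac{10^9\, C}{N\, L},$$

with `C` the fragments assigned to a gene in one library, `N` the library's
total mapped reads and `L` the gene's exon length (`compute_fpkm()`). `N`
defaults to the column sums of the count matrix, but can be overridden: in
a real experiment the reads mapped to the whole genome exceed those
assigned to annotated genes.

Without replicates no dispersion can be estimated, so differential
expression is a fold-change rule (`call_degs()`): with pseudocount
$\varepsilon$,

$$FC = \frac{\mathrm{FPKM}_t + \varepsilon}{\mathrm{FPKM}_c + \varepsilon},$$

a gene is up-regulated when $FC \ge f$ and down-regulated when
$FC \le 1/f$, with $f = 2$ — the boundary included, matching the "2-fold or
higher" convention. Two guards stabilise the rule at low expression, both
configurable because neither is dictated by the published description:

* $\varepsilon = 1$ FPKM by default. Ratios of near-zero FPKM values are
  noise; one FPKM is the conventional detection floor.
* an expressed-gene prefilter (FPKM $\ge 1$ in at least one of the two
  compared samples); genes failing it are left uncalled.

`intersect_degs()` forms the co-up- and co-down-regulated sets of two
comparisons (M0-vs-M10 and M0-vs-M20), the sets that drive every
downstream enrichment. Percentages everywhere are reported by
`fraction_report()`, which rounds half-up to one decimal — the convention
of the study's tables (14/120 prints as 11.7, where banker's rounding
would give 11.6).

## Profile normalisation and clustering

DEG profiles are made comparable by `normalize_expression()`: per gene,
$w_i = \log_2(v_i + 1)$ followed by a z-score,
$V' = (w - \bar w)/\mathrm{sd}(w)$. Two numerical choices:

* the **sample** (n − 1) standard deviation is used, so a three-sample
  profile `(1, 3, 7)` maps exactly to `(-1, 0, 1)`;
* constant profiles, which cannot be scaled, map to zero vectors with a
  warning rather than NaN.

A row-sum variant (`method = "rowsum"`) is provided purely for sensitivity
checks against the z-score transform.

Clustering is Lloyd's K-means, best of `n_init = 10` random restarts with a
recorded seed (`cluster_expression()`). K is chosen by maximising the mean
silhouette width over `k_range = 2:12` under Euclidean distance
(`select_k()`), ties breaking to the smaller K. The search range is a
package default: eight clusters are reported for the real data, but the
searched range is not, and nothing in the pipeline privileges K = 8 —
whether the original K was silhouette-selected or fixed a priori cannot be
determined from the published description, so both paths (`select_k()`
then `cluster_expression()`, or a fixed K) are supported.

Note a geometric fact that shapes everything about clustering three-sample
profiles: after z-scoring, every profile lies on a one-dimensional circle
(the unit sphere of the mean-zero plane of $\mathbb{R}^3$). Clusters are
therefore arcs, and cluster identity is an angle.

## Promoter extraction and motif scanning

Promoters are the 1000 bp immediately upstream of the TSS on the gene's
coding strand (`extract_promoters()`): for a `+` gene with TSS $t$, bases
$[t-1000,\, t-1]$; for a `-` gene the reverse complement of
$[t+1,\, t+1000]$. Promoters are clipped (and flagged) at contig edges and
are *not* masked against neighbouring gene bodies — the published
description is silent on masking, and unmasked extraction is the simpler,
reproducible choice. Internally coordinates are handled 1-based closed to
match GFF3; BED export is 0-based half-open.

Motifs are IUPAC consensus strings scanned by exact degenerate matching
with overlaps counted (`match_iupac()`, built on Biostrings). Scanning
covers both orientations by default, as plant cis-element catalogues
(AGRIS/PLACE) are conventionally strand-agnostic; a flag disables it.
Enrichment consumes **carrier status** (does the promoter contain at least
one occurrence), not occurrence counts (`carrier_table()`), matching the
"promoters of N genes" phrasing of the original counts.

## Over-representation testing

GO terms and motifs share one statistic (`hypergeom_upper()`): the
inclusive upper tail of the hypergeometric distribution,

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(M, K, n),$$

equal to the one-sided Fisher's exact test on the 2×2 table. The sum is
accumulated in log space via `lchoose`, shifted at the modal term, so deep
tails keep full relative accuracy; the suite verifies agreement with
direct pmf summation to 1e-12 relative error exhaustively for all
$M \le 60$.

Defaults mirror the original analysis: raw p-values against
$\alpha = 0.05$, background = all annotated genes (the genome-wide scan),
GO annotations taken as given without ancestor propagation.
Benjamini–Hochberg adjustment and an expressed-genes background are
available and recommended for new analyses. The TF-family table (Fig.-4
style counts) is a plain set-join (`tf_crosstab()`), not a test.

## Validation statistics

`relative_expression()` implements delta-delta-Ct:
$\Delta Ct = \overline{Ct}_\mathrm{target} - \overline{Ct}_\mathrm{ACTIN1}$,
relative level $2^{-\Delta Ct}$, and log2 ratio versus the control
condition $-(\Delta Ct_\mathrm{cond} - \Delta Ct_\mathrm{ctrl})$.
`concordance_regression()` is OLS of RNA-seq log2 fold changes on qPCR
ratios with Pearson r.

Root gravitropism angles are binned `[0,30]`, `(30,60]`, `(60,90]`,
`(90,∞)` (`bin_angles()`). The published bins "30–60" and "61–90" leave
the point 60–61 ambiguous; the closed-open convention above resolves it
(60 falls in the lower bin) and is asserted in the tests. Group
comparisons (`group_compare()`) use Student's pooled t-test, two-sided,
as stated for the original analysis, with Welch behind a flag; stars at
p ≤ 0.05 / p ≤ 0.01. The zero-variance limits are defined explicitly
(identical constant groups give t = 0, p = 1; distinct constants give
p = 0) since the textbook statistic is undefined there. One-vs-control
tests mirror the figure annotations; SPSS-style LSD/Tukey post-hocs are
out of scope.

## The synthetic-data generator

`sim_study()` fabricates a complete study: genome and gene models
(`sim_annotation()`), promoters with planted motif carriers
(`plant_motifs()`), negative-binomial counts with planted DE and cluster
structure (`sim_counts()`), GO and TF-family tables, a qRT-PCR Ct table
(`sim_qpcr()`) and a gravitropism table (`sim_gravitropism()`), plus the
ground truth for all of it. Design choices, in order of consequence:

**Counts.** Negative binomial with dispersion 0.05 — low, because single
libraries carry no replicate variance, only technical/counting noise.
Per-gene means are proportional to baseline expression × exon length and
are scaled per condition so expected column sums equal the library sizes
(10 M fragments by default; no depth is published, so this is a package
choice). That scaling reproduces a real pathology of single-library FPKM:
when up-regulation dominates, every null gene's apparent fold change
drifts slightly downward (library composition). The generator therefore
gives null genes a wide expression range (mean counts 500–50 000) and
planted DE genes moderate baselines (500–1200), keeping the planted DE
mass a small fraction of the library so the drift stays second-order —
as it is in a genome-scale experiment, where DEGs are a few percent of
genes, not forty.

**Cluster prototypes.** Eight prototypes are equally spaced directions on
the z-score circle (`cluster_prototypes()`, offset π/8, log2 amplitude
2.5). Equal spacing is the planted-truth analogue of "eight distinct
co-expression patterns"; the offset is chosen so that every prototype's
per-comparison log2 effect is either ≥ 2.15 or ≤ 0.46 in absolute value —
planted effects sit well clear of the 2-fold calling boundary, so DE truth
is unambiguous. The amplitude (≈ 6-fold swings) reflects strong
responders; it is also what "well-separated" must mean at dispersion 0.05,
where each log2 profile entry carries ≈ 0.46 SD of noise. Exactly two
prototypes are up in both treatments and two down in both (equal spacing
forces this), so the printed 314 co-up / 51 co-down genes are planted as
254 + 60 and 26 + 25 across those prototype pairs.

**Motif carriers.** All promoters are first rewritten from a GC-only
alphabet; designated carriers then receive one concrete instance of each
motif at a random position, instances kept non-adjacent. Since every
catalogue motif contains A or T in all its expansions, rescanning recovers
the designated carrier sets *exactly* — printed carrier counts (46/51,
9/51, 79/95/266 of 314) are constructible, not merely approximable. The
cost is realism: GC-only background is nothing like a rice promoter, and
the generator warns if a user motif could match a GC-only background. No
carrier count is printed for the two W-box variants ("enriched" only), so
their defaults (130 and 110 of 314) are invented.

**qPCR and angles.** Target Ct drops one cycle per planted doubling
against a fixed-mean reference, so delta-delta-Ct inverts exactly at zero
noise; per-well noise is normal (default SD 0.2 cycles, 3 replicates).
Angles are normal around the published group means (55.9°, 71.9°, 66.5°,
66.4° for M0/M10/M20/M50), SD 10°, n = 30 per group, clipped to [0°, 90°]
— curvature after a 90° reorientation is physically bounded.

**Problem sizes.** The packaged checks run at 2000 genes (about 7.8 Mb of
genome), 20 independent studies for the recovery suite, 2000 draws for
the null-calibration suite, and 36-gene qPCR panels — sizes at which every
planted signal is comfortably detectable and the whole suite runs on a
laptop in a few minutes. The real experiment (~28 000 rice genes) differs
in scale, not in structure.

## What the synthetic checks do and do not show

Passing recovery tests show that the *implementation* is faithful: the
fold-change rule finds the planted effects, silhouette selection finds the
planted K, the scanner finds exactly the planted carriers, the
enrichment test holds its nominal size under a true null. They do not
show that the *method* is optimal for real data. In particular:

* fold-change calling without replicates cannot separate biological
  variation from treatment effect; the planted truth here has none of the
  former;
* the NB noise model has no GC bias, no mappability structure, no isoform
  ambiguity (the generator emulates gene-level counts, not reads);
* GC-only promoter backgrounds eliminate accidental motif matches that
  real promoters are full of; real carrier fractions are far noisier;
* raw p < 0.05 across dozens of motif × set tests invites false positives;
  the BH option exists for a reason.

## Reproducibility

Every stochastic stage takes an explicit integer seed (`sim_study()`,
`select_k()`, `cluster_expression()`, all generators); a study object plus
a seed reproduces the entire analysis bit-for-bit, and identical seeds
produce byte-identical FASTA/GFF3 output. `scripts/acceptance.R`
regenerates the headline numbers from scratch for any seed.
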