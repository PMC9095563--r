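---
title: "ptrOmics: methods and design notes"
author: "ptrOmics maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ptrOmics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptrOmics)
```

# The scientific question

Steady-state mRNA abundance confounds two regulatory layers: how fast a gene
is transcribed and how stable its transcripts are. Run-on sequencing assays
(ChRO-seq/PRO-seq) measure the positions of actively transcribing RNA
polymerase and therefore read out transcription directly; RNA-seq reads out
the steady state; small RNA-seq reads out the miRNA pool. When a gene's
steady-state mRNA drops while its transcription is unchanged, the gene has
*gained post-transcriptional suppression* (GPS); the mirror case is a *loss*
of post-transcriptional suppression (LPS). If one upregulated miRNA's
predicted target sites are over-represented among the GPS genes, that miRNA
is a candidate *master regulator* of the response. ptrOmics implements this
integration end to end, together with a synthetic-study generator that
plants all of these effects so that every stage can be validated by
recovery.

# Gene-body quantification of polymerase positions

ChRO-seq signal arrives as stranded single-base intervals: each record marks
the 3' end of a nascent RNA, i.e. the polymerase position, with the BED
score carrying a collapsed read count. RNA polymerase accumulates just
downstream of the transcription start site (the promoter-proximal pause
peak), which would dominate gene-level counts. Counting therefore uses a
truncated *gene body*: on the plus strand `[start + 500, end)`, on the minus
strand `[start, end - 500)`, in 0-based half-open coordinates. Genes shorter
than 1000 bases are excluded outright, because removing a fixed 500-base
pause region biases against short genes.

Two conventions deserve explicit statement because the boundary cases are
tested against them:

* Intervals are half-open. A polymerase position exactly 500 bases
  downstream of the TSS is the *first* counted base.
* The length filter applies to the full annotated span (TSS to TES), which
  is the plainer reading of "gene bodies of less than 1000 bases"; the
  alternative (truncated body at least 1000 bases) is available as
  `lengthFilterOn = "body"` in `truncateGeneBodies()`.

A record overlapping several eligible gene bodies counts once per
overlapped gene; no assignment heuristic is attempted. Gene spans are the
union of transcript spans when the annotation has no gene-level records,
which matches the body-wide nature of run-on signal.

# The negative-binomial differential-expression core

Counts for gene $g$ and sample $j$ are modelled as
$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
$\log \mu_{gj} = x_j^\top \beta_g + \log s_j$, where $s_j$ are
median-of-ratios size factors and the design is `~ batch + condition`
(`~ condition` when only one batch is present). The Wald statistic for a
contrast is the coefficient over its expected-information standard error,
with two-sided normal p-values and Benjamini-Hochberg adjustment across
genes. This is the standard NB machinery; the package deliberately does
*not* reproduce any particular implementation's refinements — no
independent filtering, no outlier rejection, no fold-change shrinkage. The
contract is calibration (null rejection rate, p-value uniformity), not
bit-equivalence with another tool.

## Dispersion estimation

Three stages per gene:

1. **Gene-wise method of moments.** With normalized counts
   $y = K/s$ and within-cell residual variance $s^2$ (cells are the
   distinct covariate combinations of the design),
   $\hat\alpha_{\mathrm{gw}} = \max\{(s^2 - \bar y\,\overline{1/s})/\bar
   y^2,\,10^{-8}\}$; the $\overline{1/s}$ term removes the Poisson part on
   the normalized scale.
2. **Trend.** Ordinary least squares of $\hat\alpha_{\mathrm{gw}}$ on
   $a_0 + a_1/\bar y$ over genes with $\bar y > 1$.
3. **Shrinkage.** $\hat\alpha = \exp\{w \log \hat\alpha_{\mathrm{gw}}' +
   (1-w) \log \hat\alpha_{\mathrm{tr}}\}$ with $w = 0.5$, where
   $\hat\alpha_{\mathrm{gw}}'$ is the gene-wise value clamped to
   $[\hat\alpha_{\mathrm{tr}}/1.5,\; 8\,\hat\alpha_{\mathrm{tr}}]$.

The clamp is the one numerically consequential choice. At three replicates
per group the gene-wise estimator has about four residual degrees of
freedom; its downward excursions are almost entirely sampling noise, and
plugging them into the Wald test inflates the null rejection rate at the
0.05 level to roughly 0.09. Deviations *above* the trend, by contrast, can
reflect genuinely overdispersed genes, so the window is asymmetric: tight
from below, loose from above. With the clamp the measured null rejection
rate is 0.053-0.056 across seeds and the null p-value distribution is
uniform to a Kolmogorov-Smirnov distance of about 0.01 at 10000 genes. The
final estimate always lies between the gene-wise and trend values, so the
shrinkage remains monotone and interpretable.

## Fitting and degenerate inputs

Each gene is fitted by iteratively reweighted least squares with the
dispersion held fixed (weights $\mu/(1+\alpha\mu)$, log link, offsets
$\log s_j$), initialized at $\eta = \log(y + 0.5)$ and iterated to a
relative coefficient change below $10^{-8}$ (at most 100 iterations). The
implementation is checked in the test suite against `stats::glm.fit` with
the `MASS::negative.binomial` family on random problems. Genes that fail to
converge — in practice separation, e.g. all zeros in one group — are
refitted once with a +0.5 pseudocount and flagged; genes that still fail
are reported `NA`. All-zero genes are never tested and propagate `NA`
through to the significance lists.

Two caveats that the tests encode explicitly:

* Median-of-ratios normalization assumes most genes are not differentially
  expressed. Heavy one-sided differential expression shifts the median and
  biases every fold-change; recovery tests therefore plant effects in a
  minority of genes (and symmetrically where bias matters).
* The unshrunken fold-change estimator tracks its information bound. At
  dispersion 0.05, mean 500 and three replicates per group the per-gene
  standard deviation is about 0.27 log2 units, so the expected absolute
  error is about 0.21-0.23; no smaller error should be expected of any
  unbiased estimator under these conditions.

## Significance thresholds

Differential calls use the published thresholds as strict inequalities:
adjusted p < 0.05, |log2 fold-change| > 0.5, and baseMean > 500 for RNA-seq
and small RNA-seq volcano calls (ChRO-seq differential-transcription calls
use the same p and fold-change cuts without the baseMean floor). baseMean
is the mean of size-factor-normalized counts across all samples in the
comparison.

# Two-factor integration and GPS/LPS classification

"Post-transcriptionally regulated" is operationalised as a significant
assay-by-condition interaction: RNA-seq and ChRO-seq counts for the same
contrast are concatenated and fitted jointly with
`~ assay + condition + assay:condition` (plus `batch` when both assays
share the batch structure), with size factors computed within assay because
sequencing depths of different assay types are not comparable. The Wald
test on the interaction coefficient asks whether the steady-state response
differs from the transcriptional response; BH adjustment is applied across
genes, and the interaction reading is the package's resolution of an
ambiguity — a per-gene post-transcriptional p-value requires some such
contrast, and the interaction is the minimal one.

A gene is then classified, with thresholds following the two-stage
published definition (adjusted p cutoffs of 0.2 for the PTR stage):

* **GPS**: interaction padj < 0.2, transcriptionally unchanged (ChRO
  baseMean > 100 and ChRO padj > 0.2), changed at steady state (RNA
  baseMean > 100, RNA padj < 0.2) with RNA log2FC < -0.5.
* **LPS**: the mirror image with RNA log2FC > 0.5.
* **transcriptional**: ChRO padj < 0.05 and |ChRO log2FC| > 0.5 (the
  stricter differential-transcription thresholds; both cutoffs are exposed
  in the configuration).
* **unchanged** otherwise; **untestable** when any component statistic is
  missing (gene absent or all-zero in one assay).

Categories are mutually exclusive by construction: GPS/LPS require ChRO
padj > 0.2 while transcriptional requires ChRO padj < 0.05. Negating every
RNA-only effect swaps GPS and LPS counts exactly, which the tests assert.

Fold-change concordance between assays (a QC readout, not an inference) is
the Pearson correlation of log2 fold-changes over genes with RNA baseMean
above 500.

# Seed sites, conservation, and Monte-Carlo enrichment

## Canonical site vocabulary

For a miRNA with seed $s$ (mature positions 2-8), let $m_7$ be the reverse
complement of $s$ in DNA alphabet. On the mRNA sense strand the canonical
sites are `8mer` = $m_7$+"A", `7mer-m8` = $m_7$, and `7mer-A1` =
$m_7[2..7]$+"A". This is the minimal standard vocabulary; no 6mers, no
supplementary 3' pairing, no context scoring. At overlapping loci only the
highest-priority class is reported (8mer > 7mer-m8 > 7mer-A1); overlaps
within a class are all kept, and `N` bases never match. Matching is
exact-string, which is why UTR ingestion uppercases and maps U to T.
The scanner is verified against an exhaustive overlap-aware k-mer scan on
random 10 kb sequences.

## Conservation

A site in the reference species (rat) counts as conserved when, for the
same gene and miRNA, at least two of human, mouse and dog carry at least
one canonical site of any class in their UTR of that gene. Conservation is
presence-based, not position-aligned: no cross-species UTR alignment is
assumed or required, and a species lacking the UTR simply fails to support
the site.

## Enrichment statistic

A gene list is scored by conserved target-site *density*: total conserved
reference-species sites for the miRNA across the list, divided by the list
size (genes without a UTR count in the denominator). The null is
Monte-Carlo: 1000 random gene lists of the same size drawn uniformly
without replacement from the background universe — expressed genes (RNA
baseMean > 100) possessing a rat UTR — with the empirical p-value
$(\#\{\text{null} \ge \text{observed}\} + 1)/(n_{\mathrm{perm}} + 1)$.
Ties count as extreme and the plus-one correction is applied, so the
smallest attainable p is $1/1001 \approx 0.000999$ and the statistic is
conservative under heavy ties. The same permuted lists are reused across
miRNAs of one analysis (a common variance-reduction device), and BH
adjustment is applied across the tested miRNAs. The GPS enrichment stage
tests exactly the miRNAs called significantly upregulated in the matching
contrast and also reports the fraction of list genes with at least one
conserved site.

# The synthetic study

`simStudyConfig()` defaults describe the study conditions used throughout
the tests: 2000 genes and 20 miRNAs; two conditions (control, treated) with
three replicates each in two balanced batches; NB dispersion 0.05; baseline
means log-uniform on [200, 2000] (RNA and ChRO share baselines so the
interaction test isolates planted discordance; the geometric centre ~630
keeps planted genes above the baseMean > 100 classification floor, so
recovery measures the method rather than the abundance filter); planted
|log2FC| of 1.5; 10% transcriptionally regulated genes (half up, half
down), 5% GPS, 5% LPS; per-batch-per-gene multiplicative lognormal batch
effects (sigma 0.1) and per-sample lognormal depth factors (sigma 0.15);
five differentially expressed miRNAs (three up, including the master, two
down — planting several keeps "the master ranks first" a non-trivial
claim); UTRs of 600 bases; master-miRNA conserved sites planted in 80% of
GPS genes against a 5% background targeting rate per miRNA.

Construction details that make recovery exact rather than approximate:

* UTR backbones are uniform-random DNA from which every accidental
  canonical match for any simulated miRNA is scrubbed before planting, so
  site counts are fully controlled. Planted sites are 8mers placed on a
  non-overlapping 8-base grid; each planted site goes into rat plus two
  randomly chosen other species, making it conserved by construction.
* ChRO-seq signal is emitted as single-base BED records drawn uniformly
  within each truncated gene body, one record set per intended count, so
  `countSignal()` reproduces the intended ChRO matrix *integer-exactly* —
  the counting path is validated end to end, not statistically.
* Everything derives from one seed; the same configuration and seed
  reproduce every study file byte-identically. Signal paths inside the
  metadata table are relative to the study directory for the same reason.

What the generator does **not** emulate: isoform structure and alternative
TSS choice, UTR evolution (conservation is planted, not evolved), read-level
artefacts (no FASTQ, no mapping noise), correlated gene-gene expression
structure, and GC or length biases. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to the full messiness of real libraries.

# Pipeline, determinism and problem sizes

`runPipeline()` drives: annotation truncation, ChRO counting (from
per-sample BEDs or a precomputed TSV), per-contrast DE on all three assays,
the interaction test and classification, and GPS enrichment; it writes
per-stage TSVs, a `summary.json` whose content is deliberately
timestamp-free so reruns with one seed are byte-identical, and a log with
versions, seeds and the full parameter echo. Configuration is YAML with
unknown keys rejected by name and all thresholds defaulting to the
published values. A single global seed fans out to per-stage seeds through
a fixed affine map modulo $2^{31}$, so stages are individually
reproducible; stage functions are exported and consume the persisted TSVs,
which is how partial reruns are supported. Any stage failure aborts with
the stage name and the location of partial outputs.

The validation suite runs the default study at full size (2000 genes), the
calibration study at 10000 genes, the counting oracle on 100 random
instances (up to 50 genes and 5000 records), the seed-match oracle on 1000
random 10 kb sequences with 20 seeds, and the null-study control over 20
seeded replicates — sizes chosen to keep the whole suite in the
tens-of-minutes range on a single core while leaving each statistical
assertion well-powered.

# Known limitations

* The two-factor interaction is one defensible reading of "two-factor
  analysis"; composite definitions (e.g. intersecting marginal tests) would
  call slightly different gene sets.
* Wald tests with plug-in dispersions are approximate at n = 3; the
  dispersion clamp restores calibration on average but individual genes
  with genuinely sub-trend dispersion lose a little power.
* Conservation by presence in two species is permissive; it does not
  distinguish orthologous site positions.
* The enrichment background should match how the list was derived; the
  default (expressed genes with a rat UTR) is appropriate for GPS lists but
  is configurable for other uses.
* miRNA quantification, read alignment and isoform-level quantification are
  upstream of this package and out of scope.
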