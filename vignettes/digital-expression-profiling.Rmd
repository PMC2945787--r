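---
title: "Digital expression profiling of multi-library EST collections"
author: "estDGE"
output: html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estDGE)
```

# The setting

Before microarrays and RNA-seq were routine for non-model organisms,
transcriptomes were sampled by single-pass sequencing of clones from
cDNA libraries (expressed sequence tags, ESTs). When several
*non-normalized* libraries are built from cells grown under different
conditions, the number of cDNAs observed for a transcript in a library
is a digital measurement of its expression there: comparing counts
across libraries is differential-expression analysis. estDGE implements
that analysis chain for a transcriptional-unit (TU) by library count
matrix: per-library diversity, an omnibus log-likelihood statistic with
a randomization-calibrated cutoff, profile clustering and ordination,
annotation overlays, and codon-usage analysis, together with a synthetic
generator that plants known truth for validation.

The motivating data are collections of order 10^5 cDNAs over ~16
libraries of 3,5\-12,5 thousand clones each, from a diatom grown under
contrasting nutrient and stress regimes; the package is agnostic to the
organism.

# The data model

`ESTCountSet` extends `SummarizedExperiment` with a single `counts`
assay of nonnegative integers, TUs as rows and libraries as columns.
Two invariants are enforced at construction: no duplicated identifiers,
and no all-zero rows — a TU enters the catalogue only by being observed.
The *library size* N~j~ is always the column sum, recomputed rather than
trusted from any file, so every statistic below is self-consistent with
the matrix at hand.

Counts are compared across libraries after conversion to frequencies
f~ij~ = x~ij~/N~j~ (`normalizeFrequencies()`), which removes the
library-depth differences. `libraryStats()` reports per-library
redundancy as 100 (1 − TUs/cDNAs), the fraction of cDNAs that re-observe
an already-seen TU. The published summary table shipped with the package
(`libraryTable()`) retains the original `%R` column for reference; that
column does not follow the explicit formula above for every library and
its exact definition is undocumented in the source material, so the
package always reports the formula-based value.

# Diversity: rarefaction and Simpson's reciprocal index

Libraries of different depths cannot be compared by raw TU counts.
`rarefy()` computes the expected number of distinct TUs in a
without-replacement subsample of size m analytically,

$$E[S_m] = \sum_i \left(1 - \frac{\binom{N-n_i}{m}}{\binom{N}{m}}\right),$$

with the binomial-coefficient ratios evaluated in log space
(`lchoose`), so libraries of tens of thousands of cDNAs pose no
overflow problem. A library is under-saturated when the curve still
rises at m = N; further sequencing would then reveal new TUs. The
default grid is 20 evenly spaced subsample sizes.

Evenness is summarized by Simpson's index in its without-replacement
form, D = Σ n(n−1) / (N(N−1)), the probability that two cDNAs drawn
from the library hit the same TU, reported as the reciprocal 1/D.
Two finite-sample behaviors are worth knowing. First, an all-singleton
library has D = 0; the reciprocal is reported as `NA` with an
`undefined` flag rather than `Inf`, so tables and plots never receive
non-finite values. Second, because the formula is the *unbiased*
estimator, the reciprocal of a perfectly even library slightly exceeds
the TU count k (it equals k + (k−1)/(n−1) for k TUs of n copies); the
attainable bound is k(N−1)/(N−k), not k.

# Differential expression: the R statistic

For a TU with counts x~j~ across libraries of sizes N~j~, let
p = Σx~j~ / ΣN~j~ be its pooled frequency and λ~j~ = N~j~ p its
expected cluster size in library j. The log-likelihood ratio

$$R = \sum_j x_j \ln\frac{x_j}{\lambda_j}, \qquad 0\ln 0 \equiv 0,$$

compares the saturated per-library-frequency model against the shared-p
model. R = 0 exactly when every library's frequency equals p; R grows
as counts concentrate in fewer libraries, and scales linearly under
joint scaling of counts and sizes. **The natural logarithm is used
throughout**: any fixed numeric cutoff (such as the reference value 12)
is meaningful only under this convention.

## Calibrating the cutoff

Rather than relying on asymptotics — counts are small and libraries
unbalanced — the cutoff is calibrated by Poisson randomization
(`calibrateCutoff()`): for every TU, null counts x\*~ij~ ~ Poisson(λ~ij~)
are drawn independently per library, R is recomputed, and the pooled
null distribution over all TUs and (default 1,000) replicates yields
the empirical cutoff at `quantileTarget` (default 0.96, i.e. a flagged
TU has a 96% chance of not being a random fluctuation). Three details:

* all-zero null draws are redrawn, because every observed cluster is
  nonempty and R requires Σx ≥ 1;
* the null is pooled across clusters — the quantile is a single global
  number, matching how a single cutoff is applied to all TUs;
* the largest null R is recorded; beyond it null exceedance was never
  observed, which is the empirical analogue of "the probability of an
  R above ~2x the cutoff is zero".

On synthetic data at the published library sizes the calibrated 0.96
cutoff lands close to 12 natural-log units, the fixed reference value
also supported by `catalogueDifferential(x, cutoff = 12)`.

## Cataloguing

`catalogueDifferential()` applies two rules beyond the cutoff. TUs with
three or fewer supporting cDNAs in total are filtered
(`filtered_low_count`) and never called, whatever their R: a 3-copy TU
concentrated in one library is as likely an artifact as a signal. The
filter is applied at cataloguing, so every TU still receives an R
value. Called TUs are assigned to the libraries with the top two
highest frequencies; ties are broken by library column order (a
documented, deterministic choice — input column order is meaningful),
and a library where the TU is absent is never assigned, so
single-library TUs get a single assignment. The inequality is R ≥
cutoff (non-strict). `constitutiveSet()` returns the complementary
catalogue: TUs present in every library with R below the cutoff.

# Profile clustering and ordination

`hierarchicalCluster()` clusters TUs or libraries on their frequency
profiles with uncentered Pearson correlation distance and average
linkage — the defaults of the classic Cluster/TreeView toolchain, which
the export format targets — delegating the agglomeration to
`stats::hclust` on an in-package distance matrix. Frequencies are used
as-is (not log-transformed); with EST counts the many zeros make log
transforms awkward, and the uncentered correlation already judges
profile *shape*. `exportTreeview()` writes the CDT/GTR/ATR triple for
Java TreeView with scores stored as 1 − merge height.

`correspondenceAnalysis()` is the primary ordination: chi-square
standardized residuals of the table are decomposed by SVD, items are
placed in principal coordinates, and each axis carries an inertia
fraction; the total inertia is the chi-square statistic over the grand
total. CA is preferred over plain PCA here because the data are a
nonnegative contingency-like table and the quantities interpreted
downstream are exactly the axis inertia fractions; `profilePCA()` is
provided as an alternative. Degenerate tables (all rows proportional)
return zero total inertia and no axes rather than an error.

# Annotation overlays

`classifyPofPdf()` partitions TUs into proteins with defined functions
(at least one InterPro domain) and proteins with obscure functions (no
recognizable domain). `goEnrichment()` screens GO terms for
over-representation in a DE set against the expressed background with
the one-sided Fisher/hypergeometric upper tail; following the original
screen design it applies **no multiple-testing correction by default**
(raw P < 0.001), with Benjamini–Hochberg available via `adjust = "BH"`.
The annotation table is taken as given — no GO-DAG propagation is
performed; term assignment is the job of upstream annotation tools. The
background set is always caller-supplied and the DE set must be a
subset of it. `classProfile()` and `cogSummary()` overlay phyletic
classes and COG categories as mean frequencies; `orthologOverlap()`
counts how a DE set maps into a second species through an ortholog pair
table.

# Codon usage

`codonCounts()` tallies sense codons for CDSs that start with ATG, are
in frame, unambiguous, and free of internal stops (terminal stops are
ignored); everything else is excluded with a reason. RSCU is the count
relative to equal usage within the synonymous family (family sums equal
the degeneracy; unobserved families are `NA`, not zero). CAI weights
derive from the pooled usage of a highly expressed reference set —
genes supported by more than 30 cDNAs, with the expression index
defaulting to the *sum* of counts across libraries (`stat = "max"` is
available). Codons unobserved in an observed reference family receive a
0.5 pseudo-count before RSCU, avoiding zero weights while penalizing
rare codons. CAI is the geometric mean of weights over a gene's codons
excluding the single-codon families ATG and TGG, hence the
"59 informative codons" (61 sense − 2) used by `codonCA()`, which runs
the shared CA engine on the gene x codon RSCU table (missing families
imputed at the no-information value 1). Only the standard genetic code
ships, but the code table is injectable internally.

# The synthetic generator

`simulateLibraries()` emulates the statistical structure the analysis
assumes: log-normal base abundances (default σ = 1.5, which reproduces
heavy-tailed cluster-size distributions where the top TU reaches
thousands of copies), per-class abundance multipliers (core genes
higher than species-specific ones), multiplicative fold-change spikes
(default 5% of TUs at 8-fold in one library each), a small constitutive
set planted flat at the 99th abundance percentile, and per-library
counts drawn **multinomially conditioned on the exact library size** —
so column sums match the configured sizes, while the Poisson view of
the null lives in the calibration. Annotations load a handful of GO
terms onto spiked TUs at a configurable factor; `simulateCDS()` plants
a codon-bias gradient toward C-ending (else G-ending) codons;
`simulateOrthologPairs()` plants a conserved-responder fraction.

What the generator does *not* emulate: sequencing error and chimeras,
library-construction and cloning biases, 3'/5' coverage effects, or
any correlation structure between TUs. Passing tests therefore
demonstrate that the statistics behave as designed on data matching
their model assumptions — not that those assumptions hold for any
particular real library.

# Numerical choices and problem sizes

* Binomial coefficients in rarefaction are computed via `lchoose`.
* The calibration quantile uses R's default empirical quantile
  (type 7); with ≥10^5 pooled null values the interpolation choice is
  immaterial.
* Frequency ties in library assignment and inter-cluster ties in
  agglomeration resolve to the lowest index, for determinism.
* CA discards axes with singular values below 1e-10 of the largest.
* Validation in the test suite runs at a 5,000-TU pool over 16
  libraries at the published sizes with 100 calibration replicates —
  large enough that the 0.96-quantile cutoff stabilizes within a few
  percent across seeds, and small enough to keep the suite quick;
  the full 1,000-replicate default remains the recommendation for real
  analyses.

# Known limitations

* The R statistic is omnibus: it flags departure from a shared
  frequency but does not itself say which contrasts drive it beyond the
  top-two-frequency assignment.
* The Poisson null conditions on the observed pooled frequency of each
  TU; very low-count TUs contribute a discrete, spiky null, which is
  why the low-count filter exists.
* No FDR machinery beyond the randomization cutoff is provided for DE
  (by design); the enrichment screen's raw-p default mirrors the
  original analysis and should be tightened via `adjust = "BH"` when
  many terms are tested.
* Rarefaction assumes exchangeable draws within a library; it cannot
  correct biases that affect which transcripts were clonable in the
  first place.
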