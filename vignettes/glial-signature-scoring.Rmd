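---
title: "Methods: signature scoring of glial phenotypes in developmental-ethanol RNA-seq"
author: "gliaScore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scoring of glial phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaScore)
```

# Scope and model

gliaScore analyses bulk RNA-seq experiments in which neonatal mice receive
ethanol or a control treatment and cerebellar tissue is profiled at two
early postnatal timepoints (P5 and P6, i.e. 24 h and 48 h after the first
dose). The design is balanced and litter-structured: six animals per
treatment group per timepoint, three male and three female, drawn from
three litters so that every litter contributes to both groups. Timepoints
are always analysed independently — no cross-timepoint model is fitted.

The analysis chain is:

1. **Filter** lowly expressed genes: keep genes with raw CPM at or above a
   threshold in at least a minimum number of samples.
2. **Normalize** with trimmed-mean-of-M-values (TMM) scaling factors and
   transform to log2 counts per million (log2-CPM).
3. **Differential expression**: per-gene ordinary least squares on
   log2-CPM for the Ethanol − Control contrast, empirical-Bayes variance
   moderation, moderated t-statistics, Benjamini–Hochberg (BH) adjustment.
   Genes at adjusted p < 0.05 are called significant.
4. **Signature scoring**: each curated phenotype gene set (microglia
   homeostatic/neurodegenerative; astrocyte acute-injury /
   chronic-neurodegenerative / pan-injury; oligodendrocyte
   OPC/COP/NFOL/MFOL/MOL stages; positive/negative regulators of the G1-S
   and G2-M cell-cycle transitions) is intersected with the significant
   genes, each surviving transcript is z-scored across all animals of the
   timepoint, the z-scores are averaged per animal, and the two groups are
   compared by a two-tailed pooled-variance Student's t-test.
5. **Exploration**: sample PCA, hierarchical clustering of significant
   genes on Pearson-correlation distance, and volcano classification
   (adjusted p < 0.05 and |log2FC| ≥ 0.5).

# The average-z signature statistic

For a signature *S* and the log2-CPM matrix *X* restricted to one
timepoint, each gene *g* in *S* (after the DE gate) is standardized across
the *n* animals:

\[ z_{gs} = \frac{x_{gs} - \bar{x}_{g\cdot}}{\mathrm{sd}(x_{g\cdot})}, \]

with the sample standard deviation (denominator *n* − 1). The per-animal
score is the unweighted mean of \(z_{gs}\) over the genes, and scores are
compared between groups with the classical equal-variance t on
\(n_1 + n_2 - 2\) degrees of freedom. Two reference conventions are
supported for the standardization: all animals pooled (`zReference =
"all"`, the default — every animal is z-scored before any group split) or
Control animals only (`"control"`, expressing Ethanol scores in Control
units). Which convention a published analysis used is often ambiguous;
both are first-class here and the choice is recorded in the run config.

Two caveats are inherent to the procedure and deliberately mirrored rather
than "fixed":

* **Selection before testing.** Restricting a signature to DE-significant
  transcripts before scoring changes the null distribution of the t-test.
  The package measures the realized chain-level type-I error by
  simulation (see the acceptance test and `scripts/acceptance.R`): with a
  50-gene signature in a 2,000-gene null experiment, the BH gate at
  adjusted p < 0.05 almost never admits any signature gene, so the
  realized rejection rate of the full chain falls essentially to zero —
  the chain is strongly *conservative* under a global null, far below the
  nominal 5% (and below the 3–7% band a naive calibration argument would
  predict). Power against genuinely shifted signatures remains high
  because the gate then admits many genes.
* **No cross-signature multiplicity correction.** Per-signature t-test
  p-values are reported without adjustment across the 14 signatures,
  matching common practice for this statistic; significance stars use the
  0.05/0.01/0.001 tiers and are presentation only.

# Differential expression details

The per-gene model is an intercept plus a treatment indicator, fitted by
closed-form OLS; the coefficient is the Ethanol − Control log2-CPM
difference. Sexes are pooled with no covariate (exploratory PCA in this
design shows minimal sex structure) and litter is not modelled — a known
limitation; the simulator's `litterSd` lets users probe how sensitive
results are to litter pseudo-replication.

Variance moderation follows the standard empirical-Bayes hierarchical
model: residual variances are shrunk toward a prior
\(s_0^2 \chi^2_{d_0}/d_0\) fitted by method of moments on
\(e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)\):
\(d_0\) solves \(\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)\) and
\(s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}\). When
\(\mathrm{var}(e) \le \psi'(d_g/2)\) the prior degrees of freedom are
infinite and \(s_0^2 = \exp(\bar e)\) (note this is the bias-corrected
log-scale moment, not the arithmetic mean of the variances). The moderated
statistic is \(t = \hat\beta / (\tilde s \sqrt{1/n_1 + 1/n_2})\) with
\(\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)\) on \(d_0 + d_g\)
degrees of freedom; at \(d_0 = 0\) this is exactly the classical pooled
two-sample t, and at \(d_0 = \infty\) a normal tail is used. The tests
cross-check both the moderation fit and the statistics against limma on
random data, and the variance-abundance "trend" refinement is *not*
implemented: `mean_expr` is reported per gene so a trend could be added
later.

Numerical choices: the \(d_0\) root is found by monotone bisection of the
trigamma equation on (10⁻⁸, 10⁸) to 10⁻¹⁰ relative tolerance
(deterministic, no starting-value sensitivity); genes with exactly zero
moderated variance are excluded and listed, never given p = 0; extreme
statistics have their two-sided p clamped to the smallest positive double
rather than underflowing to 0.

# Normalization details

TMM is implemented from its published recipe: the reference sample is the
one whose 75th-percentile CPM is closest to the mean 75th-percentile;
per-gene M (log2 ratio of library-scaled proportions) and A (mean log2
proportion) are computed over genes positive in both samples; the top and
bottom 30% of M and 5% of A are discarded (rank-based, so exact ties get
average ranks); the factor is 2 to the precision-weighted mean of the
surviving M, with inverse summed asymptotic binomial variances as weights;
factors are rescaled to geometric mean 1. The implementation is verified
against an independently coded brute force and against
`edgeR::calcNormFactors` on random matrices. Because the precision weights
depend on sequencing depth, TMM factors are exactly invariant under pure
depth scaling only when M ≡ 0; under a global rescaling of one sample of a
random matrix the factors are stable to ~1% but not bit-identical, and the
tests assert accordingly.

log2-CPM is \(\log_2\{(y + c)/(\hat N + 2c) \cdot 10^6\}\) with effective
library size \(\hat N\) = raw library size × TMM factor and prior count
*c*. A single prior count (default 0.5) is used as the source of truth for
both the DE fit and the z-scoring/plots: the DE model operates on the same
transformed values the scoring sees, and a positive prior is required to
keep zero counts finite inside the per-gene OLS. `priorCount = 0` remains
available for the exact CPM identity \(\sum_g 2^{x_{gs}} = 10^6/f_s\).

The filter default `minCpm` corresponds to ~10 counts in the median
library and `minSamples` defaults to the smallest treatment-group size;
both are config-exposed, since published methods typically state only
*that* filtering occurred. Filtering and TMM do not commute with sample
subsetting in general (the reference sample can change), which is why the
pipeline filters and normalizes within each timepoint separately.

# The synthetic-data generator

`generateCounts()` draws gene × sample counts from a negative binomial
with variance \(\mu + \phi\mu^2\) and mean

\[ \mu_{gs} = m_g \cdot L_s \cdot r_{\ell(s)} \cdot 2^{\lambda_g [s \in E]} \]

* \(m_g\): per-gene baseline, log-normal with natural-log mean 5.8 and sd
  1.5 — at 19,595 genes this gives expected library sizes near 2 × 10⁷
  reads, a realistic bulk depth (the emulated study does not state its
  depth, so this is the package's declared default, not a claim).
* \(L_s\): per-sample library factor, log-normal(0, 0.2).
* \(r_{\ell}\): litter factor shared by littermates, log-normal(0,
  `litterSd`), default 0 (off) — nonzero values exist to probe
  pseudo-replication, not as a claim about the study.
* \(\phi_g\): per-gene dispersion, log-normal around
  `dispersionIntercept` = 0.05 (a typical bulk biological CV² for inbred
  mouse tissue) with log-sd 0.25 — the spread is the package's choice; a
  constant-φ model would make moderation trivially infinite-shrinkage.
* \(\lambda_g\): log2 fold change, nonzero exactly for genes of the
  signatures named in `effects`, applied in the Ethanol group only. Sex
  has no built-in effect and exists only as metadata.

All randomness uses R's Mersenne-Twister generator with inversion normals
and rejection sampling (the R ≥ 3.6 defaults, re-selected explicitly), so
a fixed seed reproduces counts bit-for-bit across sessions and platforms;
the caller's RNG state is saved and restored. Counts are stored as
integers and the ground-truth log2 fold changes travel in the
`rowData` of the returned `SummarizedExperiment`.

What the generator does **not** emulate: read-level structure (it starts
at counts), isoform usage, batch effects beyond litter, GC/length biases,
count outliers, and correlated co-expression beyond what shared litter
and library factors induce. Passing calibration tests on these synthetic
data therefore certifies the statistical machinery, not robustness to
every artefact of real libraries.

`fixtureCatalog()` provides a deterministic stand-in catalog whose *sizes*
mirror curated cerebellar collections — 822 microglial genes (split ~40/60
into homeostatic and neurodegenerative; the published split sizes are not
public, so the split is arbitrary and configurable), 309 distinct
astrocyte genes across acute/chronic/pan-injury (pan-injury deliberately
overlaps the other two, as pan-injury responses are defined to), 799
oligodendrocyte-lineage genes across five maturation stages, and four
50-gene cell-cycle sets. The memberships are synthetic gene ids; real
curated lists are supplied via GMT files (`readGMT()`).

# Problem sizes and runtime choices

The test suite exercises: TMM oracle equivalence on 100 random matrices
(≤ 300 genes × 6 samples); classical-t equivalence on 1,000 random genes
and BH on 100 random vectors; one full-scale null DE calibration (19,595
genes, 6 vs 6) checked by a 99% binomial interval around 5% and a
Kolmogorov–Smirnov uniformity test at α = 0.01; 1,000 reduced null
replicates and 200 effect replicates (2,000 genes, one 50-gene signature)
for the chain-level calibration and power/recovery checks; 1,000
property cases for the z-score contract; and byte-identity of two full
pipeline runs. These sizes keep the whole suite around two minutes on a
single CPU while leaving Monte-Carlo error well below the asserted
tolerances.

# Known limitations

* Litter is simulated but not modelled in the DE fit; with `litterSd > 0`
  the nominal type-I error of the DE stage degrades (pseudo-replication).
* No voom-style precision weights and no variance-abundance trend; very
  low-count genes rely on the filter rather than on observation weights.
* Only a single two-group contrast per timepoint; no interaction model
  across timepoints.
* The signature t-test inherits the DE gate's selection effects, measured
  (conservative under a global null) but not corrected.
* The run manifest records a wall-clock timestamp; determinism guarantees
  apply to every stage output file and to the manifest's checksum map,
  not to the timestamp line itself.
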