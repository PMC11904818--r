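---
title: "Methods: mapping the skeletal-muscle secretory niche with paired single-nucleus and spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping the skeletal-muscle secretory niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleniche)
```

# The scientific problem

Skeletal muscle is a secretory organ: fibro/adipogenic progenitors (FAPs),
muscle stem cells, myofibers and immune cells all release proteins into the
interstitial fluid, and this microenvironment shapes myofiber-type
composition and metabolism. Bulk RNA-seq averages over all of these
populations, so it cannot say *which* cells release a candidate myokine nor
whether its expression co-localizes spatially with the metabolic programs
it is suspected to regulate. Pairing a single-nucleus reference (which
resolves cell types) with Visium-style spatial transcriptomics (which
resolves position at 55-µm spot scale but mixes cells within each spot)
answers both questions, at the cost of a multi-stage analysis whose every
stage needs validation.

`muscleniche` implements that analysis as a reusable, tested pipeline, and
pairs it with a synthetic-data generator with complete ground truth —
cell-type signatures, per-spot composition, and planted gene–gene
correlations — so each stage's recovery properties are measured rather
than assumed.

# Pipeline stages and their models

## Quality control

A nucleus is kept when it expresses **strictly more than 500 genes** and
its mitochondrial count fraction (genes whose name starts with `MT-`) is
**strictly below 25%**; genes must be detected in at least one kept
nucleus. Both bounds are deliberately strict inequalities and are
configurable via `qc_params()`. The gene filter runs *after* the nucleus
filter, on kept nuclei only — the order matters and is asserted against a
brute-force oracle in the tests. Spots are filtered only on the tissue
mask; no mitochondrial rule is applied to spots by default. An optional
total-count cap (`max_counts`, off by default) offers a crude guard
against doublet-like barcodes; proper doublet detection is out of scope.

## Normalization

All expression-level work uses log2 counts-per-million:
`log2(count / library_size * 1e6 + 1)`. We deliberately do not
re-implement regularized-NB variance stabilization; log-CPM is simple,
monotone, library-size invariant (doubling every count of an observation
changes nothing), and sufficient for rank-based testing and region-level
correlation, which are the consumers here. The pseudocount of 1 maps
zeros to zero and preserves sparsity.

## Marker detection and differential expression

Markers are found one-vs-rest per population with the two-sided Wilcoxon
rank-sum test on log-CPM. A gene is only a candidate when expressed in
**more than 10%** of the population's cells and when
`|log2FC| > 0.26`, where the fold change is computed Seurat-style on
de-logged normalized means with a pseudocount of 1:
`log2((mean1 + 1) / (mean2 + 1))`. The rank-sum p-value uses the normal
approximation with tie correction, except that when **both groups have at
most 8 observations** the p is computed by full enumeration of all
`choose(n1 + n2, n1)` group assignments (doubled ranks are integers even
under ties, so the enumeration is exact); the tests check this path
against an independent dynamic-programming oracle to 1e-12.

Two-group DE on counts uses a negative binomial Wald test:
library-size-normalized counts, pooled method-of-moments dispersion
(`alpha = (var - mean) / mean^2`, floored at zero, pooled across the two
groups by degrees of freedom), a delta-method standard error on the log2
fold change, and — as this package's small-sample calibration choice — a
*t* reference distribution with `n1 + n2 - 2` degrees of freedom rather
than the normal. Under a pure NB null (10,000 genes, 50 vs 50 nuclei)
the realized type-I rate at `p < 0.05` sits within 0.05 ± 0.01, and
two-fold planted genes are detected with power above 0.9 at the pipeline's
standard thresholds (`p < 0.05`, `|log2FC| > 0.26`); both are recomputed
by `scripts/acceptance.R`. Pass/fail flags always use the **raw** p
together with the fold-change rule; Benjamini–Hochberg q-values are
reported alongside but do not gate the flags, matching how the thresholds
are stated. A caveat inherent to size-factor normalization: a fold change
shared by essentially every gene is absorbed into the size factors and is
undetectable — effects must be differential, not global.

## Secretome annotation and the comparison screen

A DEG is called secretory when any of its subcellular-location strings
contains a secreted keyword (case-insensitive substring, default
`"Secreted"`, so "Secreted, extracellular space" matches). Annotation is
an identifier lookup into a provided location table — deliberately not a
sequence-similarity search, which would be database-version dependent and
unreproducible; the table is a file input with gene ids as primary keys.
Genes absent from the table are flagged distinctly
(`in_location_table = FALSE`) rather than silently treated as negative.

The screen intersects two or more *signed* DEG sets (each comparison's own
up/down convention), reporting the common genes, the direction-consistent
subset, and each comparison's private genes; a gene listed both up and
down within one comparison is a validation error, and the partitions are
checked against naive set algebra.

Gene-set enrichment is the hypergeometric upper tail
`P(X >= k)` for overlap `k` between the query and a set of size `K`
inside a universe of size `N` with query size `n`, BH-corrected across
sets with significance at `Q < 0.05`, and reports the rich factor `k/K`.
The universe defaults to the genes surviving QC in the contrasted dataset;
whether to use all annotated genes instead is exposed as the `universe`
argument, since reasonable analysts differ here.

## Deconvolution and FAPs-high/low regions

Cell-type signatures are per-population mean CPM profiles from the
labelled reference, restricted to the union of the top-k up-markers per
population (k = 50 by default). Each spot's CPM profile is then regressed
on the signatures by **non-negative least squares** and the coefficients
are normalized to sum to one. NNLS against mean signatures is the
simplest estimator whose output — a per-spot composition — is all the
downstream analysis consumes; topic-model deconvolution is a non-goal,
and an externally produced proportion table can be substituted anywhere a
`proportion_map` is accepted. All-zero spots fall back to uniform
proportions and are flagged. On synthetic tissue at the generator's
default noise the mean absolute error against true proportions is about
0.02, versus the 0.05 acceptance bound.

Spots are classified by the **type-1 (order statistic) empirical
quantiles** of the FAPs proportion over the sample's in-tissue spots:
at or above the 0.75 quantile is FAPs-high, at or below the 0.25 quantile
is FAPs-low, otherwise intermediate. The order-statistic quantile makes
ties at the threshold fall into the extreme class (with 100 distinct
proportions, exactly 26 spots are high), and the labelling is invariant
to monotone rescaling of the proportion column. The quantile cutpoints
are fully configurable; the source study gives no threshold, so quartiles
are this package's default.

## Random-region correlation (the core procedure)

The defining step asks whether a secretory gene's expression co-varies
spatially with myofiber-type markers and metabolic genes. Direct
spot-level correlation is dominated by per-spot sampling noise, so the
procedure aggregates: draw many equal-area regions at random, form each
region's pseudo-bulk profile, and correlate genes across regions.

* A **region** is a uniformly drawn in-tissue seed spot plus its 24
  nearest in-tissue neighbours by Euclidean pixel distance (exact ties
  broken lexicographically by barcode, so membership is deterministic).
  A fixed 25-spot size keeps all regions at equal area; on tissue edges
  the 25 nearest spots simply reach further inward.
* The default design draws **200 regions per sample** and pools samples,
  giving 400 regions for the two-sample study. Overlap between regions is
  allowed — forbidding it would make 200 regions infeasible on a
  ~2,000-spot tissue.
* Each region profile is the log2-CPM of the summed member counts.
* For each (secretory, target) pair, the Pearson `r` across regions with
  the two-sided p from `t = r * sqrt((n-2)/(1-r^2))` at `n - 2` degrees
  of freedom. Two tiers flag interesting pairs: standard
  (`|r| > 0.4`, `p < 0.05`) and strict (`|r| > 0.5`, `p < 0.001`).
  Zero-variance genes yield records flagged undefined, never a fabricated
  r. Per-condition (e.g. per-breed) r values are reported next to the
  pooled r; the tier flags use the pooled statistics.

The degrees-of-freedom caveat is intentional and documented rather than
corrected: overlapping regions are not independent samples, so the
t-based p is anti-conservative with respect to spatial autocorrelation.
The tier thresholds on |r| (not only p) are what carry the screening
burden, which is also how the thresholds are used in practice.

# The synthetic-data generator

The generator emulates the structure of the real study so that every
stage above is testable without any download:

* **Reference** (`simulate_reference()`): 8 populations named after the
  major muscle populations (FAPs, myofibers, MuSCs, myoblasts, pericytes,
  endothelial, myeloid, lymphoid), 150 nuclei each, 1,200 genes with
  negative binomial counts (dispersion size 2), 20 markers per population
  elevated 2^3-fold over a baseline mean of 1.5, and 10 `MT-` genes at
  mean 8 (a ~4% mitochondrial fraction). Five percent of nuclei are
  simulated as low-quality (all means shrunk 5-fold, so they fail the
  500-gene rule) and two percent as mitochondria-dominated (mito means
  boosted 12-fold, failing the 25% rule), so QC keeps roughly 93% of
  nuclei — comparable to the ~90% retention typical of real muscle
  snRNA-seq. These knobs exist so the QC stage has genuine work; their
  values are ordinary for the tissue, not fitted to anything.
* **Spatial samples** (`simulate_visium()`): a 10x-dialect hex grid
  (`array_col` parity equals `array_row` parity; pixel coordinates are an
  affine map giving a 100-µm center-to-center lattice) with an elliptical
  tissue mask. Per-spot composition comes from one spatial field per
  population: white noise, Gaussian-blurred at length-scale
  `proportion_smoothness` (default 1.5 spot units), standardized,
  exponentiated, and normalized across populations — positive,
  sum-to-one, spatially autocorrelated, which is all the downstream
  stages require of it. A zero length-scale is the degenerate
  structure-free case: every spot gets identical expected proportions.
  Spot expression is `proportions x signatures`, rescaled so every spot's
  expected library is `reads_per_spot`, with NB sampling (size 20).
* **Planted correlations**: each pair (a, b, rho) receives smooth latent
  log-scale factors — one shared, one private per gene, mixed with
  weights `sqrt(|rho|)` and `sqrt(1-|rho|)` (the shared factor's sign
  flipped for negative rho) — so the correlation of the two genes' latent
  log-means is exactly rho. Because region pseudo-bulk log-CPM is nearly
  linear in these log-scale offsets, the region-level Pearson r
  concentrates on rho with mild attenuation from counting noise. The
  latent fields use their own length-scale (`planted_smoothness`,
  default 1.0), kept finer than the composition field; a pilot
  simulation set this default so that the tissue holds enough independent
  patches of planted signal for region correlations to concentrate.
* **Annotation and gene sets**: a location table with a configurable
  secreted fraction (planted secretory genes always annotated secreted)
  and random GMT gene-set collections.

Everything is bit-reproducible: each generator takes one integer seed and
restores the global RNG state afterwards; the pipeline derives per-stage
seeds from a single global seed by hashing the stage name
(`derive_seed()`), so any stage can be re-run independently.

## What the generator does *not* emulate

No doublets, ambient RNA, batch effects, UMI-level read structure, breed
differences, or histology. Passing tests therefore demonstrate that the
*machinery* is correct — filters match their stated rules, estimators
recover planted truth at realistic noise — not that the pipeline is
robust to every artifact of real tissue. In particular the two synthetic
samples are exchangeable by construction, so the between-condition DE
contrast in the bundled analysis is a true null and its empty DEG list is
the correct answer, exercised as such.

# Statistical design notes

* **Why 400 pooled regions for recovery checks.** With n regions, the
  sampling floor of an empirical correlation is about `(1-rho^2)/sqrt(n)`
  even for a perfect generator; at n = 200 and rho = 0 that is 0.071, so
  demanding `|r - rho| <= 0.15` in 95% of replicates is marginal by
  construction for a single sample. The study design this package
  reproduces pools 200 regions from each of two samples; at n = 400 the
  floor drops to 0.05 and recovery concentrates well inside the band.
  The recovery tests therefore measure the pooled two-sample design —
  the design the procedure is actually run with.
* **Problem sizes in the test-suite.** The suite checks QC against a
  brute-force oracle on 50 random fixtures of up to ~400 nuclei; exact
  Wilcoxon against full enumeration over every group-size combination up
  to 8 vs 8; DE calibration on 10,000 null genes at 50 vs 50; deconvolution
  on a 36x36-grid tissue; and correlation recovery over 50 seeds of two
  80x80-grid samples (about 5,000 in-tissue spots each, the scale of the
  real samples) with 200 regions per sample. These sizes were chosen as
  the smallest at which the measured properties are stable.
* **Numerical conventions.** Strict inequalities exactly as stated for
  every threshold; type-1 quantiles for region classification;
  lexicographic tie-breaks for region membership; BH for every q-value;
  undefined statistics flagged, never imputed.

# Known limitations

* NNLS against mean signatures ignores spot-to-spot library-size
  heteroscedasticity and gene-gene covariance; it is unbiased in the
  noiseless limit but not efficient.
* Region-correlation p-values do not correct for region overlap or
  spatial autocorrelation (see above); treat them as screening
  statistics, as the tier thresholds do.
* The method-of-moments NB dispersion is per-gene with no shrinkage;
  at very small group sizes the Wald test will be less calibrated than
  at the 50-vs-50 design it is validated on.
* `"Secreted"` keyword matching is only as good as the supplied location
  table; multi-compartment annotations count as secreted if any
  compartment matches.
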