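---
title: "Methods: enrichment scoring, pooling, survival and spatial procedures in atf6scope"
author: "atf6scope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment scoring, pooling, survival and spatial procedures in atf6scope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atf6scope)
```

# Scope and model

atf6scope implements the analysis chain used to quantify ATF6α
transcriptional activation in liver cancer: a paired up/down gene signature
is scored per sample, the tumour/non-tumour contrast is pooled across
datasets, the score stratifies survival, and orthogonal readouts come from
spatial single-cell imaging and cross-species copy-number concordance. Each
stage is an explicit function; nothing depends on hidden state, and every
stochastic step draws from a seed carried in the simulation spec.

## Signature and per-sample scoring

A signature is built from a differential-expression table by
`|log2FC| >= 1` (inclusive) and BH-adjusted `p < 0.05` (strict). Both
thresholds are parameters; the defaults reproduce the mouse-derived
activation signature rule (which yields 888 up- and 266 down-regulated
genes on the original contrast).

Per-sample enrichment is ssGSEA: genes are ordered by decreasing expression
within the sample, and the score is the summed difference between the
weighted in-set cumulative distribution (rank weight `(N - i + 1)^alpha`,
`alpha = 0.25`, normalized to 1) and the uniform out-of-set distribution.
Two consequences worth knowing:

* the score depends only on the within-sample ordering, so any strictly
  monotone transform of a sample's values leaves it unchanged — this is why
  the synthetic cohorts can use plain Gaussian log-expression;
* scores grow with gene count and set size; only contrasts of the same
  configuration are comparable, which is all the pipeline needs.

One scorer is used everywhere. The upstream study scored one figure with a
different rank-based per-sample method (GSVA); we deliberately standardize
on ssGSEA for all stages and record the scorer in output metadata, since
the downstream contrast is invariant to which of the two rank-based scores
carries it. Genes in a set but absent from the matrix are dropped with a
warning, never zero-filled — phantom zeros would distort the ranks. Ties in
expression are broken by ascending gene id, a measure-zero event in real
data that makes the ranking total and deterministic.

The combined activation score is exactly `ES_UP - ES_DN`, antisymmetric
under swapping the sets.

## NTP classification

Samples are called activation-high or -low by nearest-template prediction:
templates are +1 on UP genes and -1 on DN genes (and the negation), the
distance is 1 minus the Pearson correlation over signature genes, and
significance comes from `n_perm` random gene sets of matched sizes, with BH
FDR < 0.05 flagging confident calls. Genes are z-scored across the cohort
first (the GenePattern convention): without standardization, between-gene
baseline differences dominate the template correlation and the call
degenerates toward chance. The trivial template-equal geometry can be
checked with `standardize = FALSE`.

## Information coefficient

The IC is `sign(rho) * sqrt(1 - exp(-2 I))` with `I` a mutual-information
estimate from a bivariate Gaussian KDE on a 25x25 grid. For jointly
Gaussian data `I = -log(1 - rho^2)/2`, so IC reduces to Pearson's rho; the
KDE adds sensitivity to non-linear dependence. Two numerical choices
matter:

* bandwidths are the normal reference (`MASS::bandwidth.nrd`) times 1.5 —
  the reference rule undersmooths for MI estimation and inflates the null
  (independent data would otherwise show |IC| up to ~0.3 at n = 200);
* bandwidths shrink by `(1 - 0.75 |rho|)`, following the estimator's
  lineage, so that perfectly dependent data approach |IC| = 1 instead of
  saturating near 0.88.

With these choices, at n = 200: IC(x, x) > 0.98, independent data give
|IC| < 0.2 with insignificant permutation p, and a quadratic dependence
yields |IC| far above |rho|. Constant input defines IC = 0 with a warning.

## Meta-analysis

Per dataset the effect is Hedges g of the combined score between tumour and
non-tumour samples — the small-sample-corrected standardized mean
difference, chosen because cross-platform score scales differ and SMD is
the canonical random-effects input. Pooling is plain DerSimonian–Laird:
moment estimate of the between-study variance truncated at zero,
inverse-(v + tau^2) weights, and a normal 1.96 CI (no Knapp–Hartung
adjustment, matching the plain estimator named by the method). When the
moment estimate truncates to zero the procedure reduces exactly to
fixed-effect inverse-variance pooling, and the pooled estimate always lies
within the range of the inputs.

A caution the package makes explicit: the planted *per-gene* effect size of
the expression simulator is not the *score-level* SMD — averaging dozens of
shifted genes inflates the score contrast severalfold. Recovery of the DL
machinery is therefore tested on `gen_score_panel()`, which plants the SMD
directly at the score level; the expression-level panel is checked
qualitatively (positive pooled effect, finite per-dataset g).

## Survival

The stratification chain is: administrative censoring (records beyond the
horizon become alive-at-horizon; the operation is idempotent), median split
of the score with ties assigned to the low group (so "high" is strictly
above the median; 370 distinct scores give 185 per group), Kaplan–Meier
product-limit curves, and the Mantel–Cox log-rank test. The censoring
horizon defaults to 60 months; the source description of the rule carries
an internally inconsistent parenthetical ("180 days"), and the months
figure governs here, exposed as `cutoff_months`. KM and the log-rank
statistic are computed through the survival package; the tests re-derive
both from the product-limit and hypergeometric definitions and compare the
chi-squared p against a 10,000-draw permutation null.

## IMC spatial stack

Cytoplasm is literal pixel-set subtraction of nuclei from cells, labels
inherited. Compartment mapping assigns a nucleus (or cytoplasm) to the cell
containing its "most central" coordinate, implemented as the pixel-rounded
centroid — with the member pixel nearest the centroid substituting when the
centroid falls off the object, which makes the rule total for non-convex
shapes. If several nuclei land in one cell, the largest pixel-overlap wins
and the others stay unassigned; nuclei centred on background stay
unassigned; every cell emits a record regardless.

Gating is threshold-at-or-above on per-compartment mean intensities, with
thresholds supplied by the caller (the source procedure gated manually on
histograms; nothing is auto-fitted). Lineages come from ordered flag rules,
first match wins. Region-level ATF6-hi/low classification defaults to a
median split of the positive-cell fraction across regions (ties to low,
consistent with the survival split) because the original criterion is not
quantified; an absolute cutoff can override it.

Neighborhoods use radius `1.5 x` the mean equivalent-circle diameter
(`2 sqrt(area/pi)`) of the cells in the image — per image, not global,
since the source does not say and per-image adapts to magnification. The
neighbor relation is centroid-to-centroid, boundary inclusive, hence
symmetric; profiles are lineage frequencies among neighbors, and the
aggregate reports mean composition per index lineage.

## MIBI QC and normalization

The filter applies the study's fixed thresholds: area < 71 px or
> 3,318 px, nuclear sum intensity below 9.21 a.u., nuclear proportion
outside 0.3–99.8%. The quoted percentile parentheses describe how those
constants were once derived; here the constants are the defaults and all
are parameters. Bounds are inclusive on the keep side ("< 71" and "below
9.21" exclude strictly). Cells tripping several rules count once per rule
and once in the total, so per-rule counts can exceed distinct exclusions.
Normalization is exactly the enumerated chain — cap at the marker's
99.9th percentile across retained cells (type-7 quantile), multiply by 10,
arcsinh; no further normalization precedes the cap because none is
specified. Group comparisons are the two-sided Mann–Whitney U and
two-sample Kolmogorov–Smirnov tests.

## CNA synteny

Mouse CNA-positive regions pair with their human homologues through an
explicit key map (one-to-many allowed, unmapped regions reported). A pair
is concordant when the human same-type carrier frequency strictly exceeds
5% — "exceeds" is strict, so exactly 0.05 is discordant, and an absent
frequency counts as zero. The 2x2 table contrasts the CNA-type pairs with
a caller-supplied background stratum subjected to the same rule; the
background is the procedure's one genuinely unstated degree of freedom, so
it is an explicit input (the simulator plants one at a configurable rate).
The Fisher test is the exact two-sided point-probability method (sum of
hypergeometric probabilities not exceeding the observed, relative
tolerance 1e-12), verified against full enumeration and
`stats::fisher.test`.

# The synthetic-data layer

The generators define the conditions the pipeline is validated under:

* **Expression** (`gen_expression_cohort`, `gen_multi_dataset`): Gaussian
  log-scale values, per-gene baselines, 50 samples per group, 22 datasets,
  UP genes shifted `+0.8` noise-SD in tumours (DN negated), per-dataset
  baseline shifts, optional effect heterogeneity `tau`. Signature sizes
  scale the 888/266-of-20,000 proportions down to the simulated gene count.
  Rank-based scoring makes the Gaussian choice innocuous.
* **Scores** (`gen_score_panel`): the SMD-level substrate for meta-analysis
  recovery (see above).
* **Survival** (`gen_survival_cohort`): exponential event times with hazard
  `h0 exp(beta z)`, `h0` fixed by a 30-month baseline median, n = 370,
  uniform censoring on a 120-month window for a 30% censor fraction —
  desk-scale stand-ins for a TCGA-sized cohort.
* **Tissue** (`gen_tissue_image`): hard discs of radius 5 px (area 81 px at
  that radius), concentric half-radius nuclei, rejection-sampled
  non-overlap with bounded retries, three lineages at 50/25/25%, per-pixel
  lognormal intensities whose log-means differ by 4 pixel-SD between own
  and other markers. Cell-level means then separate almost perfectly,
  which is what makes >= 99% gating recovery a fair bar.
* **CNA** (`gen_cna_dataset`): deterministic per-type planting of the
  concordant fraction (frequencies drawn strictly above/below the 5% line)
  so contingency counts are exact, plus a background stratum at 10%.
* **MIBI features** (`gen_sc_feature_table`): in-range baseline cells with
  planted violations that each trip exactly one rule.

What the simulators do **not** emulate: marker spillover, segmentation
errors, doublets, batch effects beyond mean shifts, non-exponential
hazards, deformable cell shapes, and real linkage between genomic position
and CNA frequency. Passing recovery tests therefore demonstrates the
*procedures* are correct and calibrated under their stated models, not
that the biological conclusions transfer to any particular real dataset.

# Problem sizes and determinism

The shipped tests and the acceptance script run at sizes chosen to exercise
the asymptotics that matter while staying comfortably reproducible on one
CPU: 100 replicates for CI coverage (10 datasets x 50/group), 200
replicates for survival type-I (n = 370), 10,000 permutations for the
log-rank null, all 2x2 tables with margins <= 10 for Fisher enumeration,
50 random instances for the ssGSEA oracle, and 100-cell tissues for the
spatial oracles. Every generator consumes an explicit seed and restores
the caller's RNG state, so identical seeds give bit-identical outputs.

# Known limitations

* ssGSEA scores are not min-max rescaled; cross-configuration score
  magnitudes are not comparable (by design, as noted above).
* The IC estimator's bandwidth constants are calibrated for n in the
  hundreds; far smaller samples will inflate |IC|.
* The NTP null uses random gene sets of matched sizes, which assumes
  exchangeability of genes within a sample's profile.
* DL pooling with few datasets (k < ~10) runs liberal, a known property of
  the plain estimator; the package reports tau-squared and Q so users can
  judge heterogeneity.
* The tissue simulator's hard discs cannot probe mapping behaviour on
  overlapping or concave cells beyond the synthetic non-convex cases in
  the tests.
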