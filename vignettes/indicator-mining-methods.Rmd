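---
title: "Mining stable microbial indicators of reef water chemistry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining stable microbial indicators of reef water chemistry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Free-living seawater bacteria and archaea respond to their chemical
environment within hours to days, which makes them attractive sentinels
for reef condition. Two obstacles stand between that idea and a usable
monitoring tool. First, geography and season confound naive
community–environment associations: samples collected on the same voyage
share both a sector of the reef and a time of year, so a taxon that
tracks a voyage tracks everything that voyage carried with it. Second,
functional redundancy — many taxa encoding the same metabolic functions —
means the *taxon* associated with, say, particulate nitrogen can differ
from trip to trip even when the *function* is associated every time.

`reefmarkers` implements an integrated workflow for this setting:
compositional preprocessing of annotated read-count tables (taxa at genus
level, and gene-function terms), community summaries, a
geography-corrected screen of which physico-chemical variables structure
the community at all, multi-study sparse regression to extract indicator
features that associate with those variables *consistently across trips*,
and two resampling-based stability scores that quantify how reliable each
indicator is. A synthetic-data generator with known ground truth makes
every stage testable end to end.

# The model pipeline

## Compositional preprocessing

Sequencing counts are compositional: only relative information is
meaningful, and library sizes vary. After rule-based filtering
(unannotated, eukaryote, virus, and domain-level-only features are
removed, then features below an overall relative abundance of
10^-6^ = 0.0001%), counts are mapped to real space with the centered
log-ratio (CLR) transform,

$$v_{ij} = \ln(x_{ij} + c) - \frac{1}{p}\sum_k \ln(x_{ik} + c),$$

with pseudocount $c = 1$ by default (log of zero is undefined for raw
counts). CLR rows sum to zero; all multivariate analyses (PCA, sPLS)
operate on this scale, while Bray–Curtis dissimilarities are computed on
relative abundances, where that metric is defined.

Two interpretation choices the underlying data format leaves open are
settled as follows and are configurable: the rare-feature threshold is
applied to the *overall* dataset fraction (feature total over grand
total, computed after the class rules), not per sample; and the natural
log is used for both CLR and Shannon diversity.

## Screening variables: partial Mantel tests

For each of the 17 physico-chemical variables and each dataset (taxa,
gene functions), the association between community dissimilarity
(Bray–Curtis on site-level relative abundances) and environmental
distance (Euclidean on the unit-SD-standardized variable) is tested
while controlling for between-site geographic distance (haversine, Earth
radius 6371.0 km). The statistic is the Spearman partial correlation of
the lower-triangle entries — equivalently the correlation between the
residuals of the two rank regressions on geography. Inference permutes
rows and columns of the community matrix simultaneously (10,000
permutations by default), one-sided for positive association, with
Bonferroni correction within each dataset's 17 tests. Environment
variables are standardized before the Euclidean distance so that units
do not dominate; both this choice and the Bonferroni family (per-dataset
by default, global available) are recorded in the results.

## Extracting indicators: sparse PLS with multi-study integration

Sparse partial least squares (sPLS) regresses the response block Y
(CLR-transformed features) on the predictor block X (the 17 variables;
each sample carries its site's median environment values). Per
component, the algorithm seeks unit loading vectors $(a, b)$ maximizing
covariance between $Xa$ and $Yb$, with all but the $k$ largest-magnitude
entries of each loading zeroed; the kept entries are soft-thresholded by
the $(k{+}1)$-th magnitude. Iterations start from the dominant singular
pair of $M = X^\top Y$; after each component X and Y are deflated on the
X-score (regression mode). With the sparsity disabled the first
component equals the top singular pair of $M$ exactly, which the test
suite verifies against an independent singular-value decomposition, and
on tiny instances the selected subset is verified against brute-force
subset enumeration. Defaults follow the workflow the package supports:
two components, 50 responses kept per component, all 17 predictors kept.

Multi-study integration (MINT) addresses the trip confound: every column
of X and Y is centered and scaled *within each trip* before a single
shared loading set is estimated on the concatenation. Trip-level offsets
— seasonal chemistry shifts, batch effects in sequencing — are removed
by construction (adding any per-trip constant to any column leaves the
fit unchanged), so the selected features are those covarying with the
environment consistently across trips.

Indicator heatmaps use the similarity
$\mathrm{sim}(i,j) = \sum_h \mathrm{cor}(X_i, t_h)\,
\mathrm{cor}(Y_j, t_h)$ over retained components, with rows and columns
ordered by complete-linkage clustering on Euclidean distance and cut
into three community-type clusters by default. The X-score $t_h$ is used
for both blocks (the single-variate convention); sign flips of a
component leave the similarity unchanged.

## Scoring stability

Two complementary resampling schemes quantify indicator robustness:

* **Leave-one-group-out (LOGOCV).** One fold = one trip. The MINT model
  is refitted four times, each time with one trip held out, and each
  feature's score is the fraction of refits (denominator: the number of
  trips) in which it was reselected on component 1. With four trips the
  scores are 0.25 (trip-specific, unstable), 0.5, 0.75 or 1
  (shared/stable); the 15 nonempty selection patterns partition into
  4/6/4/1 scenarios at those levels.
* **Repeated fourfold CV within a trip.** For each of the eight
  (trip × dataset) models, the samples of that trip are split into four
  folds, the model refitted on each complement, and this is repeated 50
  times — 200 runs per model. Stability is the reselection frequency of
  each of the 50 full-fit component-1 indicators. Taxa-vs-function
  stability within a trip is compared with a two-sided Wilcoxon rank-sum
  test (exact when both sides have at most 8 untied values).

LOGOCV refits reuse the full fit's keep values so selection sizes stay
comparable, and selection is assessed on component 1 only. Fold
partitions are uniform random without stratification, all derived from
one master seed.

# The synthetic-data generator

The generator emulates the structure of a four-trip, 48-reef-site survey
with four replicate samples per site, and is the package's test bed:

* **Environment.** 17 variables in two collinear blocks — particulate
  nutrients plus pigments, and dissolved N/P — with within-block
  correlation 0.7 and a cross-block correlation of −0.4 (production
  draws down dissolved pools), plus stand-alone variables (TSS,
  temperature, salinity). Each trip adds block-level seasonal offsets
  (SD `batch_sd`). Standardized latent values are mapped onto
  plausible oligotrophic-reef measurement scales; a configurable number
  of cells (default 2) is masked as missing.
* **Abundances.** Taxon log-abundances are Gaussian (log-normal
  abundance structure, baseline SD 1.5) with per-trip batch offsets
  (SD `batch_sd`) and per-sample noise (SD `noise_sd`); counts are
  multinomial over the softmax of the latent values at a Poisson library
  size. This makes the data compositional by construction, matching the
  CLR geometry of the pipeline.
* **Redundancy and planted signal.** Each GO term sums `redundancy`
  member taxa (default 4; the taxon-to-function map is decoupled from
  the taxonomy). For each of the 40 planted indicator GO terms, one
  designated env variable drives the group's latent abundance with slope
  `effect_size` (in CLR units per env SD). Which member taxon carries
  the signal rotates across trips: the designated member's weight is
  $k/(1+(k{-}1)\gamma)$ and the others carry $\gamma$ times that
  ($\gamma = 0.5$), scaled so the *group sum* responds with slope
  `effect_size` in every trip while each member taxon is strongly
  associated in only one trip. This single mechanism yields both planted
  properties the tests verify: ordinary least squares on a planted GO
  term's CLR values recovers `effect_size` within ±25%, and the per-trip
  GO–environment correlation exceeds the average member-taxon
  correlation.

Defaults — `effect_size = 1`, `noise_sd = 1`, `batch_sd = 1`,
`rotation_gamma = 0.5`, `library_size_mean = 1e5` — were fixed once as a
realistic regime: a planted within-trip correlation of roughly
$1/\sqrt{2}$, batch shifts of the same order as the signal, and library
sizes giving hundreds of reads per moderately abundant feature. No field
study reports its effect sizes on this scale; these are calibration
choices and are documented as such.

What the generator does *not* emulate: read-level error, taxonomy
database artifacts, distance decay of community similarity within a
trip, overdispersion beyond the log-normal latent noise, and structured
(non-random) missingness. Passing tests therefore demonstrate that the
machinery recovers known structure under a faithful-but-idealized model,
not that any particular real reef dataset will behave the same way.

# Numerical choices and degenerate inputs

* sPLS convergence: loading change below 10^-6^ (up to a common sign
  flip), at most 100 iterations; non-convergence returns the model with
  a warning. Component signs are fixed by making the
  largest-magnitude X-loading positive. Selection ties at the boundary
  break by feature order.
* Zero-variance columns: set to zero (with a warning) during scaling;
  their correlations in similarity matrices are 0.
* Zero-sum samples are an error for relative abundance; all-zero vector
  pairs are an error for Bray–Curtis; constant distance matrices are an
  error for Mantel tests, except that a *constant geographic matrix*
  degenerates gracefully to the simple Mantel statistic.
* Missing environment cells are excluded pairwise in distance and
  scaling computations and imputed by the within-trip median before
  sPLS (falling back to the overall median).
* Permutation p-values use the add-one convention
  $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$, so they are
  never zero.

# Problem sizes used in the tests

Unit and property tests run the generator at a reduced size (4 trips ×
6 sites × 4 replicates, 120 taxa, 30 GO terms) that preserves every
structural property; the acceptance checks of the design counts and the
direction-of-effect results use the full 48-site design (600 taxa,
150 GO terms, 5 seeds for the stability contrast) with the full
200-run CV per model. Permutation-test calibration uses 500 null
simulations at 199 permutations each. These sizes were chosen so the
whole suite completes in a few minutes while leaving the Monte-Carlo
bands (type-I error within [0.03, 0.07] at $\alpha = 0.05$) tight
enough to be informative.

# Known limitations

* The per-trip sPLS models inherit the environment table's site-level
  resolution: replicates within a site share one environment row, so
  the effective predictor sample size is the number of sites.
* With strongly collinear environment blocks, which *single* variable a
  Mantel screen flags within a block is partly arbitrary; the screen is
  a variable-level summary, not a causal attribution.
* LOGOCV with four trips gives a four-level stability score; it
  separates trip-specific from shared indicators but cannot rank within
  the shared group finely.
* The generator's rotation mechanism is the *minimal* redundancy model;
  real functional redundancy involves many-to-many gene-taxon maps and
  horizontal transfer, which are out of scope.
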