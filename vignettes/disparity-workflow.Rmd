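---
title: "Quantifying morphospace evolution from cladistic matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphospace evolution from cladistic matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Palaeontologists summarize the anatomical variety (*disparity*) of a fossil
clade from the same discrete character-taxon matrices built for phylogenetic
analysis. `cladospace` implements that workflow end to end: inter-taxon
dissimilarities on the cladistic matrix, ordination into a morphospace,
disparity metrics per group with resampling uncertainty, tests of group
separation, and phylogenetic regressions of morphospace position on
explanatory traits. This vignette explains the models and the numerical
choices; the README shows a worked example.

## The distance stage: MORD and WMPD

Fossil matrices are dominated by missing data (incomplete skeletons) and
inapplicable codings. The package therefore uses the Maximum Observable
Rescaled Distance (MORD): for a pair of taxa, only the characters scored in
both are compared; each raw difference (0/1 set-disjointness for unordered
characters, minimum step distance between state sets for ordered ones) is
divided by the summed *maximum observable* difference of those shared
characters — 1 per unordered character, the coded state range per ordered
character. This bounds every distance in [0, 1] regardless of how many
characters the pair shares, avoiding the inflation that generalized
Euclidean distances suffer under heavy missing data (which is why no GED
option is provided). Polymorphic cells resolve to their closest member
state (`min` rule), matching the usual convention for polymorphic terminals
in parsimony software; a mean rule would be a one-line change but is not
exposed because no stage downstream wants it. Inapplicable cells are
treated exactly like missing cells in distances and parsimony: the states
simply cannot be compared.

The pre-ordination disparity metric is the weighted mean pairwise
dissimilarity (WMPD): pairwise distances weighted by the number of
comparable characters `n_ij`, so poorly-overlapping (hence noisy) pairs
contribute less. Because WMPD needs no complete distance matrix it is
computed on *all* taxa, including those that later have to be trimmed for
ordination.

## Ordination: PCoA with Lingoes correction

MORD matrices are generally non-Euclidean, so the double-centered
eigendecomposition produces negative eigenvalues. The Lingoes correction
adds the smallest constant `c = |lambda_min|` to all squared off-diagonal
distances that makes the matrix embeddable; eigenvalues are then
non-negative up to numerical noise (tolerance `1e-8`, the detection
threshold for "negative"). Axis signs are arbitrary in any
eigendecomposition; for reproducible output each axis is oriented so its
largest-magnitude loading is positive. Variance fractions are reported
relative to the sum of *positive corrected* eigenvalues — with the Lingoes
constant folded in, that sum is the total variance the coordinates actually
carry.

Pairs of very incomplete taxa can share no scored character at all, leaving
their distance undefined. `trim_for_ordination()` removes taxa greedily —
always the taxon involved in the most undefined pairs, breaking ties by
missing-data fraction and then name — which removes the minimum-culprit set
in the common case of a few pathological taxa and is fully deterministic.

The number of retained axes is a *user* choice made on the scree plot (the
conventions in this literature keep the axes before the last clear slope
change). The package deliberately has no automatic elbow detector: the
choice is a config value (`axes_disparity`, `axes_regression`), and
`axis_variance()` reports the cumulative variance a choice captures.

## Disparity metrics and resampling

On the retained axes three complementary metrics are computed per group
(time bin, locomotion class):

* **Sum of Variances (SoV)** — per-axis sample variances (n−1), a
  size-and-density measure robust to sample size;
* **Sum of Ranges (SoR)** — per-axis ranges, a size measure that grows with
  sampling;
* **displacement** — the mean over group members of
  `‖x − c_ref‖ / ‖x − c_group‖`, a position measure relative to a reference
  centroid (the whole dataset, or the previous time bin; the first bin has
  no predecessor and uses its own centroid, pinning its value at 1). The
  mean of the per-taxon ratios is used; `summary = "median"` is available.
  Members sitting exactly on their group centroid have an undefined ratio
  and are dropped with a warning.

Uncertainty comes from bootstrap resampling: group members are resampled
with replacement (9999 replicates by default — odd, so the percentile tails
are symmetric around a well-defined median) and the metric recomputed. WMPD
resamples taxa of the distance matrix; the post-ordination metrics resample
rows of the fixed ordination (re-ordinating each replicate would conflate
sampling noise with rotation noise). Intervals are two-tailed 2.5/97.5
percentiles, except SoR: a subsample's range can never exceed the full
sample's, so the upper tail is meaningless and the interval is one-tailed
(5th percentile below, upper limit = point estimate). Rarefied intervals
(resampling at the size of the smallest compared group, default 7)
accompany the plain ones so unequal group sizes can be ruled out as the
driver of a difference. Group differences are called significant when 95%
intervals are disjoint; touching endpoints count as overlap (the
conservative closed-interval convention). Plain percentile intervals are
used throughout — the tail rules above are defined on percentiles, and BCa
acceleration is not meaningful for the pinned SoR upper tail.

Because confidence-interval overlap is weak at detecting *position*
differences, group separation is additionally tested with a PERMANOVA
(Euclidean distances on the retained axes, free permutation of group
labels, `p = (1 + #(F* ≥ F)) / (1 + n_perm)`), via `vegan::adonis2()`.
Taxa whose stratigraphic uncertainty spans several bins are included in
every bin they span for the disparity metrics, but are excluded from the
PERMANOVA (a taxon cannot carry two labels in one permutation scheme);
the `exclusions$uncertain` config lists them.

`metric_diagnostics()` probes what a metric measures by computing it on
nested subsets grown from six different rankings (inner/outer distance to
centroid, high/low local density, top/bottom of axis 1) and regressing the
metric on the proportion kept. On a symmetric cloud the two position series
are mirror images, so a position-blind metric shows near-equal slopes
there, while size- and density-sensitive metrics separate the paired series
strongly; SoR's inner-size slope towers over its (near-zero) outer-size
slope because ranges are carried entirely by peripheral points, the sense
in which SoR is the more size-contraction-sensitive metric.

## Tree operations

* **Time calibration** (`calibrate_mbl()`): node ages start at the oldest
  descendant first-appearance age and a tips-to-root pass enforces a
  minimum branch duration (default 0.1 Myr). The two-pass rule is
  deterministic and idempotent; it concentrates ghost lineages near the
  tips rather than smearing them rootward, which is the standard
  minimum-branch-length behaviour.
* **Parsimony scoring** (`parsimony_tree_length()`): generalized Sankoff
  optimization, linear step costs for ordered characters, 0/1 for
  unordered; missing/inapplicable tips accept any state freely and
  polymorphic tips any member of their set. Tree *search* is out of scope —
  scoring a given tree is all the workflow needs.
* **Ancestral states**: discrete traits (locomotion) by Fitch
  most-parsimonious-reconstruction sets from a down-pass/up-pass
  optimization; unknown tips get their MPR set, singletons become
  imputations, larger sets stay flagged ambiguous. Across a sample of
  equally parsimonious trees each tree votes with its unambiguous
  imputation and the majority wins; ties (and all-ambiguous cases) remain
  ambiguous — aggregation across trees has no canonical rule, and majority
  voting with abstention is the least committal choice. Continuous traits
  (log body mass) use maximum-likelihood Brownian-motion estimates
  (`phytools::fastAnc`), whose root value is the GLS mean.
* **Covariance structures** (`phylo_vcv_and_tree_shape()`): the
  time-calibrated variance-covariance matrix feeds the regressions; the
  diagonal of the unit-branch-length variant counts nodes from root to tip
  and serves as a purely topological "tree shape" covariate.

## Phylogenetic regressions with RRPP

`dpgls_fit()` regresses the first few morphospace axes (default 3 — axes
beyond the scree elbow carry little variance and mostly conflict) on
explanatory variables under phylogenetic covariance: response and design
are premultiplied by `C^(-1/2)` from a symmetric eigendecomposition with an
eigenvalue floor of `1e-10` (minimum-branch-length calibration can make `C`
nearly singular). Sums of squares are trace statistics over the response
axes, all axes weighted equally, with type II comparisons (each term
against the model containing all other terms). Significance uses the
residual randomization permutation procedure: reduced-model residual rows
are permuted, the pseudo-F recomputed, and `p = (1 + #(F* ≥ F)) / (1 +
iterations)` (999 iterations by default). Categorical predictors use
treatment contrasts with the alphabetically first level as reference; R²
and p are invariant to that coding. Two predictor pairs are refused as
confounded: body mass with femoral length (strongly collinear in
archosaurs), and locomotion with the humeral/femoral circumference ratio
(the ratio is how locomotion is inferred in the first place). `model_suite()`
crosses a model list with a tree sample; because fitting 30-odd models on
hundreds of trees is expensive, the default run subsamples 10 trees
(seeded) and the full sample is one argument away. Models are compared on
R² and p; no information criterion is reported because the RRPP framework
does not define a likelihood to penalize.

## The synthetic data generator

Every stage above is exercised without any external file by
`simulate_dataset()`, which emulates the statistical structure of a
stage-binned early-dinosaur dataset:

* a **birth-death tree** (defaults: 0.35/0.33 per Myr — a high-turnover
  fossil clade — rooted at 245 Ma and run to 163.5 Ma) conditioned on 67
  tips, with tip extinction ages used as first-appearance dates. The taxon
  subsample is stratified so every stage bin holds at least 7 taxa, the
  smallest bin size the binned analyses are designed around; FADs are
  clamped into the bin window. No stratigraphic error model is layered on
  top — extinction age *is* the FAD, the simplest model satisfying the
  calibration contract.
* **419 discrete characters** evolved by continuous-time Mk simulation
  (exact event-by-event simulation, so ordered characters can only step
  between adjacent states); state counts are drawn with probability
  ∝ 0.3^(k−2) up to 4 states (cladistic characters are mostly binary), 20%
  of characters are ordered, and per-character rates are lognormal
  (median 0.002 events/Myr, giving a realistic mix of invariant, clean and
  homoplastic characters). A small polymorphism probability (0.005/cell)
  keeps the parsers and distance rules honest.
* **taxon-wise missing data**: each taxon masks cells at a
  beta(4, 2)-distributed rate scaled into [0.3, 0.95]. Missingness is a
  property of taxa (how complete the fossil is), not characters, which is
  what makes the centroid-repulsion artefact reproducible: the package's
  `missing_data_bias_test()` finds the positive correlation between
  missing percentage and centroid distance on these fixtures just as it
  does on real matrices.
* **traits**: log body mass by Brownian motion (σ² = 0.05 per Myr from a
  300 kg root, spanning a few kg to several tonnes over the window);
  locomotion quadrupedal above 500 kg with a 5% flip probability and 15%
  of taxa recorded unknown (so imputation has work to do); a slow 4-state
  Mk "continent" trait, phylogenetically clumped like real biogeography;
  femoral length and limb circumferences allometric in mass with the
  circumference ratio higher in quadrupeds.

What the generator does *not* emulate: real character correlations within
anatomical regions, directional (driven) body-size trends, stratigraphic
dating error, and the topology-dependence of character conflict. Green
tests on these fixtures therefore demonstrate that the *machinery* is
correct and calibrated (type I error, CI coverage, exact small-case
optima), not that any biological conclusion transfers to a particular real
matrix.

## Problem sizes and determinism

The default configuration mirrors a full study (67 × 419 matrix, 9999
bootstrap replicates and permutations, 999 RRPP iterations) and runs in
about a minute on one core; the test suite uses smaller replicates of the
same structures (hundreds of null simulations at n ≈ 24, small trees for
exhaustive-enumeration oracles) chosen to keep each property statistically
sharp at desk scale. Every random step — generator, bootstrap,
permutations, tree subsampling — flows from an explicit integer seed with
a fixed default (1234), and rerunning any pipeline with the same config is
bit-identical.

## Known limitations

* NEXUS/TNT parsing covers the standard discrete-matrix subset
  (DATA/CHARACTERS + ASSUMPTIONS typesets/weights, `xread` + `ccode`), not
  continuous characters, Dollo/Camin-Sokal types or program-specific
  extensions.
* The PERMANOVA excludes multi-bin taxa rather than duplicating them;
  duplication would pseudo-replicate rows and bias the permutation null.
* `calibrate_mbl()` implements the deterministic two-pass rule; other
  implementations of minimum-branch-length scaling may distribute ghost
  lineage duration differently, so calibrated branch lengths should be
  compared against a reference implementation before mixing outputs.
* Displacement ratios are undefined for taxa exactly on their group
  centroid (excluded with a warning) and unstable for groups of two.
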