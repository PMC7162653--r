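---
title: "Models and methods for lineage-dependent cortical connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for lineage-dependent cortical connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecircuits)
```

This vignette describes the statistical machinery in `clonecircuits`: what
each model assumes, which parameters matter and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## The scientific setting

Excitatory neurons of the neocortex are produced by radial glial cells
(RGCs); sparse genetic labeling of a progenitor marks a *clone* — a radially
arranged group of sibling neurons spanning layers 2–6. A labeled clone may
pool the offspring of several RGCs (here `N`, typically 1–4 with a median
of 2). Paired whole-cell recordings test directed synaptic connections
between clone members ("related" pairs: both cells labeled) and between a
labeled and a nearby unlabeled cell ("unrelated" pairs). Pairs of two
unlabeled cells are ambiguous (they could be an unlabeled clone) and are
excluded from the primary comparison, but are admitted to the
distance-matched control pool where sheer numbers matter. A tested
connection is *vertical* when the pre- and post-synaptic cells occupy
different layers and *lateral* when they share one.

## Connection probability and its comparisons

Connection probability is the number of connections divided by the number
tested; uncertainty is the exact Clopper–Pearson interval (beta-quantile
form), and group comparisons use Fisher's exact test with the
minimum-likelihood two-sided convention. These are deliberately the most
conservative standard choices for sparse binary outcomes: most
layer-defined cells of the design hold only a handful of connections.

Three complementary controls guard the headline comparison:

* **Distance-matched bootstrap** (`distance_matched_bootstrap()`).
  Connectivity falls with intersomatic distance, and related pairs are
  systematically closer than arbitrary controls. Each related pair is
  matched to controls with the same pre/post layers whose tangential and
  vertical distances lie within 20 µm (inclusive — the conventional reading
  of "within"; results are insensitive at this tolerance). Each of the
  (default 1000) iterations resamples related pairs with replacement and
  draws one eligible control per selected pair, uniformly at random — the
  selection rule is not fixed by the original description, and uniform
  selection is the least informative choice. The p-value inverts the
  bootstrap interval of the related-minus-control difference: subtract the
  observed mean difference from every bootstrap difference and count the
  shifted differences at least as extreme (two-tailed).
* **Rostrocaudal stratification** (`stratify_by_rostrocaudal()`) re-runs the
  comparison within rostral and caudal strata (default split: positions 1–3
  versus 4–5 on the 1–5 scale; the original grouping keyed on named
  cortical areas, which the numeric table does not carry, so the midpoint
  split is the package's default and any rule can be passed as a function).
* **Connectivity GLM** (`connectivity_glm()`): a Bernoulli GLM with logit
  link over tested directed pairs, with lineage `L`, connection type `C`,
  Euclidean distance `D` (µm) and rostrocaudal position `R` plus all
  pairwise interactions — 11 parameters, so residual degrees of freedom are
  `n - 11` (the published fit reports 1988 on 1999 directed tests, which is
  why the package models directed tests rather than collapsed reciprocal
  pairs). Fitting is IRLS via `stats::glm()`; non-convergence and
  quasi-separation are surfaced in `$diagnostics` and as warnings, never
  silently.

The log-ratio heatmap (`log_ratio_table()`) summarizes per-type effects as
`log2(((A+1)/(B+1)) / ((C+1)/(D+1)))` with add-one (Laplace) smoothing so
zero-connection types stay finite; its interval is a 95% coverage interval
of bootstrapped log-ratios with `A_boot ~ Binomial(B, (A+1)/(B+1))` and
`C_boot ~ Binomial(D, (C+1)/(D+1))`.

Percentages are displayed rounded half away from zero to one decimal,
matching the publication convention (note `2/89 = 2.25%` prints as 2.3%).

## The cortical-cylinder input-fraction model

A cell's potential presynaptic partners are modeled as the excitatory
neurons within a tangential radius `r` of its position. With
100,000 neurons/mm² of cortical surface, 80% excitatory, and
`r = 0.087` mm (half the 99% quantile of measured pairwise distances), the
cylinder holds `π r² × 80,000 ≈ 1902` excitatory neurons; the published
rounded count is 1908, and `cylinder_model(n_total = 1908)` pins the total
exactly (the printed radius is itself rounded, so both modes are provided
and differ by ~0.3%). Layer occupancy defaults to 35/15/25/25% across
L2/3, L4, L5 and L6. A clone of `k = 60` cells (the median clone size)
makes the related fraction `q_r = k/N_total`.

The number of inputs from each (layer, lineage) pool is binomial with the
measured connection probability, so the expected fraction of input from
related cells is

$$e = \frac{p_r\,q_r}{p_r\,q_r + p_u\,(1-q_r)}$$

— the pool sizes cancel, which `expected_inputs()` asserts numerically.
The standard error propagates the two binomial standard errors to first
order (delta method), with `p_r` and `p_u` independent because the two
lineages are measured on different pair sets.

A caveat worth stating: first-order propagation is a local approximation.
At very small numerators (e.g. 2 connections out of 89 tested) the sampling
distribution of `e` acquires an atom at `p_u = 0` (where `e = 1`), and a
parametric bootstrap of `e` has a much larger spread than the delta-method
SE. The package reports the delta-method SE as published; the test suite
verifies the bootstrap agreement at interior rates where the expansion is
valid and treats the published small-count SEs as display values.

## Lineage-pooling power analysis

If only neurons sharing a single RGC are preferentially connected (fold
change `FC` over the unrelated rate `P_ul`), pooling `N` lineages into a
clone dilutes the observable effect. Among the `S/L - 1` *other* clone
members in a cell's layer (clone size `S = 60`, layers `L = 4`, equal
lineage spread across layers), `S/(NL) - 1` share its RGC, giving the
pooled lateral prediction

$$P_{rl} = \frac{P_{ul}\,\frac{S}{L}\,\frac{N-1}{N} + P_{ul}\,FC\,\left(\frac{S}{NL}-1\right)}{\frac{S}{L}-1}.$$

The `-1` terms exclude the cell itself from its own same-RGC pool. The
same mixture for vertical connections, `P_rv = P_uv (N-1)/N + FC\,P_uv/N`,
is inverted by `infer_fc_from_vertical()` to obtain the `FC` consistent
with the observed vertical rates; `FC · P_uv` is then the implied
vertical connection probability between neurons sharing one RGC.

Effect size uses Cohen's h, `2 asin √p₁ − 2 asin √p₂`, and power the
two-sided normal approximation with unequal group sizes
(`ñ = n₁n₂/(n₁+n₂)`), matching the conventional two-proportion power tool.
Both tails are included (so `h = 0` gives power `α`); a one-sided variant
is available by flag. `power_grid()` sweeps `N` in 1–20 and `FC` in 0–30
(step 0.1; the grid resolution is a display choice) and
`inferred_fc_trace()` pins, per `N`, the `FC` implied by the vertical data.
Predicted probabilities exceeding 1 at extreme `FC` are clipped with a
warning rather than erroring, to keep grids total.

The companion sample-size helper uses `n = 2((z_{1-α/2}+z_{power})/h)²` per
group, the convention consistent with the power formula at equal sizes. The
published figures contain two derived sample-size/power numbers ("16%
probability of detecting a 50% decrease", "sample size … 233") that do not
follow from any standard two-proportion formula with the stated inputs;
the package computes the generic quantities and does not chase those two
printed values.

## Transcriptomic mapping

Query cells (Patch-seq) are compared against a large annotated reference
atlas with a fixed, precomputed 2-D embedding — the package never computes
the embedding itself, it only positions queries on it.

* **QC** (`qc_filter_cells()`): cells more than 3 MADs below the median on
  library size or genes detected are removed. **Gene filtering**
  (`filter_genes()`): genes averaging under one count per cell are removed
  (a mean of exactly one is kept).
* **Normalization** (`normalize_counts()`): size factors are library size
  over the geometric-mean library size, then `log2(x+1)`. The original
  analysis used pool-based size factors, which on these data correlate
  closely with library size; precomputed factors can be supplied for exact
  replication.
* **Variable genes** (`select_variable_genes()`): genes with counts ≥ 32 in
  fewer than 10 cells are excluded; per gene, `μ` is the mean log2 count
  over counts strictly above 32 and `τ` the fraction strictly below 32
  (counts exactly 32 enter neither, following the rule as written); a
  binary search over the offset `b` selects the target number of genes
  above `τ = exp(−1.5 μ + b) + 0.02`. The search stops on an exact hit or
  a bracket below 1e−9, returning the closest achievable count — ties on
  the curve are the only way to miss by more than one.
* **Embedding placement** (`map_cells_knn()`): Pearson correlation to every
  reference cell over the shared genes; position = coordinate-wise median
  of the 10 most correlated references. Precision
  (`mapping_precision_bootstrap()`) is the 80th percentile of displacement
  across 100 gene-bootstrap re-mappings; plotted sizes follow the
  convention precision > 10 small, 5–10 intermediate, ≤ 5 large.
* **Cluster assignment** (`assign_to_clusters()`): nearest-centroid over
  mean log profiles; ties (essentially impossible off synthetic data)
  resolve to the first label in sorted order and are flagged. Same-type
  pair fractions use exact intervals and a chi-squared comparison.
* **Region classifier** (`region_prediction_cv()`): cross-validated
  penalized multinomial logistic regression with misclassification-error
  CV (accuracy = best over the λ path), and a permutation null by label
  reshuffling. The default penalty is ridge (`alpha = 0`); the original
  analysis used the lasso path — the permutation-null framing makes the
  conclusion penalty-robust, and `alpha` is exposed.

## Synthetic data: what it does and does not emulate

`sim_config()` holds the study conditions: clones of 60 labeled cells over
2 RGC lineages, 35/15/25/25% layer occupancy, a 0.087 mm cylinder at
100,000 neurons/mm² (80% excitatory) filled with unlabeled background
cells placed uniformly in the disc (the cylinder model's homogeneity
assumption; no spatial structure is claimed for unrelated cells), and
per-type connection probabilities defaulting to the published rates.
Depth within a layer is uniform over a band proportional to the layer
fraction of a 1200 µm cortical depth — a nominal juvenile-mouse cortical
thickness; only relative depths matter downstream. Tangential distance is
the in-plane Euclidean projection, vertical distance the depth difference,
and Euclidean distance the root of the summed squares, all in µm.

Expression is negative-binomial around cluster means (disjoint marker
blocks over a common baseline) scaled by a uniform library-size factor,
with a single dispersion and a Poisson limit flag; the reference embedding
places cluster centroids on a circle with Gaussian jitter. One master seed
expands into per-operation substreams so each generator is independently
reproducible.

What passing tests on these data do **not** show: the generators draw
pair outcomes independently given their type (no clone-level random
effects, matching the analysis's independence assumption), impose no
distance dependence on connectivity (matched-control tests construct their
own geometry), and the expression model has no batch structure, no
zero-inflation beyond the NB, and no relationship between transcriptome
and connectivity. Results on real recordings and real Patch-seq libraries
can differ in all of these respects.

## Problem sizes and numerical choices

The test suite and examples run at deliberately desk-scale sizes — a few
clones, hundreds to tens of thousands of simulated pairs, hundreds of
genes/cells, bootstrap repetitions in the hundreds — chosen so every
statistical check (binomial interval coverage at 10,000 draws, GLM
parameter recovery at 20,000 pairs, 100,000-draw power simulation) retains
its Monte-Carlo resolution. Headline quantities are exact closed-form
evaluations of printed counts and involve no simulation at all.

Degenerate inputs fail loudly: empty filters, all-zero margins, zero
dispersions, zero-library cells, queries with zero variance, separated
GLMs. Where a statistic is undefined (both connection probabilities zero)
the package errors rather than returning 0/0.

## Known limitations

* The delta-method SE understates uncertainty at very small connection
  counts (see above).
* The distance-matched bootstrap conditions on the observed control pool;
  with few eligible controls per related pair its p-values become grainy.
* The cylinder model ignores layer-specific connection radii and treats
  the clone as fully contained in the cylinder.
* The GLM treats tested pairs as independent; clone-level correlation
  would widen its intervals.
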