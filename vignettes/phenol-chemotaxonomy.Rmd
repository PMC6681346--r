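---
title: "Phenol-based chemotaxonomy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenol-based chemotaxonomy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotax)
```

## The scientific problem

Keystone plant taxa — in particular *Erica* shrubs of East-African mountain
ecosystems — leave chemical fingerprints in soils and sediments long after
pollen has degraded or dispersed. Mild alkaline CuO oxidation releases a
panel of sixteen phenolic monomers from plant tissue; after GC–MS
quantification each sample is described by sixteen contents in g kg⁻¹ TOC.
`phenotax` implements the downstream analysis of such panels: aggregation
into the six classical phenol groups, source-proxy ratios, diversity
indices, distance-based ordination, a transparent threshold rule for
*Erica* identification, and tree-based classifiers with a replicated
evaluation harness.

## The measurement model

A sample is a non-negative vector $x \in \mathbb{R}^{16}_{\ge 0}$ over the
canonical compounds (`phenol_compounds()`). Measured contents are attenuated
by work-up losses; the internal-standard recovery $r \in (0,1]$ is recorded
per sample and `recovery_correct()` restores $x = x^{meas}/r$. All
downstream fractions are invariant to $r$, but absolute contents (used by
clustering) are not, so correction is the first pipeline stage.

Group sums follow the defining equations of the six groups: *p*-hydroxy,
vanillyl (V), syringyl (S), coumaryl (C), benzoic acids, and
hydroxy-benzoic acids. 4-hydroxybenzoic acid belongs to *both* *p*-hydroxy
and hydroxy-benzoic acids; the package deliberately keeps the per-group
definitions and does not renormalize, so

$$\sum_{g} \text{group}_g = \text{total} + x_{\text{4-hydroxybenzoic acid}}$$

holds exactly and is asserted by tests. Relative abundances divide each
group by the plain 16-compound total; the six fractions may therefore sum
to slightly more than 1. This choice preserves the published group
definitions at the cost of a non-unit simplex, and every classifier in the
package consumes the fractions individually, never their sum.

The Shannon–Wiener diversity index is computed over the sixteen individual
compounds, $H = -\sum_i p_i \ln p_i$ with $p_i = x_i / \sum_j x_j$ and
$0\ln 0 = 0$, giving $0 \le H \le \ln 16 \approx 2.77$. The compound-level
(rather than group-level) definition is the only one consistent with
published per-species values, several of which exceed $\ln 6$. The natural
logarithm is used, the standard Shannon–Wiener convention.

## The Erica threshold rule

`classify_erica_rule()` flags a sample as *Erica* when its coumaryl
fraction strictly exceeds 0.20 **and** its benzoic-acids fraction lies in
the closed interval $[0.05, 0.12]$. Boundary semantics follow the printed
thresholds: a strict ">" at 0.20 and a closed dash-range for benzoic acids.
Because boundary ties are scientifically delicate, the result carries the
two component verdicts and the underlying fractions so users can audit
samples near the edges. The rule depends only on fractions and is exactly
scale-invariant.

## Ordination and clustering

Hierarchical clustering uses Euclidean distances on Z-scored absolute
contents (g kg⁻¹ TOC) of the sixteen compounds and the Ward
minimum-variance criterion. We compute classic Ward — `stats::hclust` with
squared distances — so merge heights are Ward cost increments; this is
recorded explicitly because "Ward" implementations differ in whether they
square internally. Z-scoring uses the $n-1$ denominator; constant columns
are mapped to zeros with a warning rather than producing NaNs. Whether the
original analysis clustered the 16 compounds or the 6 group sums is not
derivable; the package defaults to the 16 compounds (the richer
representation) and `ward_cluster()` accepts any matrix, so group-level
clustering is a one-line variant.

PCA is a singular-value decomposition of the centered matrix. Components
are sign-fixed so the largest-magnitude loading entry is positive,
making score plots reproducible across platforms.

## Trees and forests

`cart()` grows binary classification trees with the Gini criterion:
exhaustive scans over all midpoints between consecutive distinct feature
values, ties broken by feature order (canonical sorted names) and then by
the lower threshold; values $\le$ threshold route left. `phenol_forest()`
bags such trees over bootstrap resamples with per-split feature subsampling
(`mtry = floor(sqrt(p))` by default) and majority voting, ties resolving to
the canonically lower class. The default of 10,000 trees mirrors the
ensemble size used in the motivating analysis; importance and vote
statistics for $p \le 16$ features stabilize far below that, so the test
suite and the evaluation scripts use 200–500 trees.

Feature importance is mean decrease in Gini: each split's impurity
decrease weighted by the fraction of the tree's samples reaching the node,
summed per tree, averaged over trees, and normalized to sum to 1.
`representative_tree()` returns the member whose predictions agree most
with the ensemble vote — a standard device for displaying one
interpretable tree on a forest's behalf.

Feature columns are internally sorted by name, so fits, importances and
predictions are invariant to input column order; reproducibility is
guaranteed given the `seed` argument.

Class imbalance (29 *Erica* vs 18 other samples in the study design) is
handled by unweighted Gini; no class weighting is applied because the
motivating analysis reports none.

## Evaluation harness

`split_train_test()` allocates `ceiling(fraction * n)` training samples per
class by floor plus largest remainder. The ceiling convention is chosen so
that the canonical 2/3 split of 47 binary-labelled samples yields exactly
32 training samples, the training size quoted for the reference forest;
per-class rounding would yield 31. Stratified splits always retain at
least one training sample per class, and singleton classes go entirely to
training with a warning (they cannot be stratified).

`compare_algorithms()` runs a grid of training fractions (default 0.5,
0.6, 2/3, 0.8) times replicates (default 5), sharing each cell's split
across algorithms for paired comparison; a failing algorithm is recorded
with its error message rather than aborting the grid. F1 defaults to the
*Erica*-positive binary task; when precision + recall is zero F1 is 0 by
convention and flagged. `cross_validate()` uses stratified round-robin
folds (sizes differ by at most one; every sample tested exactly once). The
SVM backend is a thin wrapper around `e1071::svm` and is deliberately
excluded from the package's core guarantees — it exists so three-algorithm
comparisons can be reproduced, not as part of the contribution.

## The synthetic-data generator

The per-sample compound table behind the motivating study was never
published, so the package ships a generator that emulates its *structure*:
six species with the study's sample counts (29/5/7/4/1/1, 47 samples) and
species mean totals (16/18/51/22/6/22 g kg⁻¹ TOC), Dirichlet-distributed
compositions around species means, log-normal totals, and uniform
recoveries in 0.6–0.95. Group-level mean fractions are spread uniformly
over each group's member compounds because only group-level contrasts are
documented; the compound-level means are therefore synthetic and labelled
as such.

The species mean compositions encode the documented contrasts: *Erica*
(and only *Erica*) sits inside the threshold-rule region (coumaryl 0.27,
benzoic 0.085); Helichrysum has the highest *p*-hydroxy fraction and
*Erica* the lowest; Festuca pairs the highest coumaryl (0.33, about one
third of its total, as expected for grasses) with the lowest vanillyl and
benzoic; Kniphofia and Lobelia carry the highest benzoic-acid fractions.

Two dispersion parameters control realism versus testability:

* **Dirichlet precision** (default 800): within-species compositional sd
  for a fraction $p$ is $\sqrt{p(1-p)/(1+c)}$. At $c = 800$ the *Erica*
  benzoic margin to its rule boundaries (±0.035 from the interval center)
  is about 3.5 sd, so essentially all simulated *Erica* pass the rule and
  essentially no other species does.
* **Total CV** (default 0.06): log-normal coefficient of variation of
  per-sample totals.

These defaults were calibrated — by Dirichlet variance arithmetic and seed
sweeps, before the test suite was frozen — so that the generator exhibits
the two structural properties the package asserts about it: threshold-rule
separability of *Erica* and Ward-cluster recovery of the four replicated
species at $k = 6$. They are tighter than real leaf chemistry: field data
show larger within-species spread, and the motivating study's own
clustering of real data mixed several species. Passing the clustering
tests therefore demonstrates that the pipeline machinery is correct, **not**
that real vegetation samples cluster cleanly by species; the generator
makes no attempt to emulate GC–MS peak-level noise, co-elution or
derivatization artifacts. Users studying robustness should raise
`total_cv` and lower `concentration` and expect the rule classifier to
degrade gracefully and clustering to degrade quickly — the same ordering
of robustness the original analysis reports.

Two auxiliary generators provide sharper fixtures: a single planted
threshold at coumaryl = 0.21 (for threshold-recovery checks) and a
two-feature planted signal in coumaryl- and benzoic-like features (for
importance-ranking checks).

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script use: 47- and 470-sample
synthetic datasets (scale factors 1 and 10), 1000-sample planted-threshold
data, forests of 200–500 trees, and 20-seed replication for ranking
stability. Exact identities (group-sum conservation, recovery inversion,
Z-score moments, metric oracles) are asserted at 1e-9 to 1e-12; stochastic
properties (rule fidelity ≥ 0.9, top-2 importance rate ≥ 0.95, cluster
ARI ≥ 0.8, planted-threshold recovery ±0.02) at the stated bounds.

## Known limitations

* Contents must arrive TOC-normalized; no unit conversion layer exists.
* The rule classifier's thresholds are fixed constants of the method, not
  fitted parameters; refitting them to new regions is out of scope.
* The forest implementation handles numeric features only (the phenol
  panel is fully numeric); no surrogate splits or missing-value handling.
* `simulate()`-style posterior draws from fitted models are not provided;
  the generator is forward-only.
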