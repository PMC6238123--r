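---
title: "Methods: phylogenetic structure and turnover of plot communities"
author: "phylocomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic structure and turnover of plot communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocomm)
```

`phylocomm` analyses plot-based vegetation surveys with a dated phylogeny of
the regional species pool.  This vignette documents the statistical models,
their assumptions, the tunable parameters, the synthetic-data generator used
for validation, and the numerical and design choices that were genuinely
open.

## Data model

Three objects enter every analysis and are harmonized into a
`CommunityData` container:

* a rooted phylogeny with non-negative branch lengths (any time units);
  multifurcations are accepted as-is, because every statistic below depends
  only on patristic (tip-to-tip path-length) distances, which are well
  defined on multifurcating trees.  Ultrametricity is *reported*
  (`ultrametricityReport()` gives the root-to-tip depth spread) but not
  enforced: a dated tree should be near-ultrametric, and surfacing the
  deviation is more informative than rejecting the input.
* a plot-by-species abundance matrix of non-negative counts;
* a plot environment table: elevation (m), latitude and optionally
  longitude (decimal degrees).

Name matching is exact string matching after trimming whitespace and
mapping spaces to underscores — deterministic and auditable; no fuzzy
taxonomic matching is attempted.  Harmonization drops (and reports) tips,
species and plots without a counterpart and is idempotent.

## Alpha structure: MPD, MNTD, and the null model

For an assemblage with pairwise patristic distances $d_{ij}$,

$$\mathrm{MPD} = \operatorname{mean}_{i<j} d_{ij}, \qquad
  \mathrm{MNTD} = \operatorname{mean}_i \min_{j \ne i} d_{ij}.$$

MPD is sensitive to deep (basal) tree structure, MNTD to structure near the
tips.  Both default to presence/absence; abundance weighting (pair-product
weights for MPD, per-species weights for MNTD) is available behind
`weighted = TRUE` because the field uses both conventions and the survey
design gives no reason to prefer one.

The null model preserves, for every plot independently, its species
richness and its multiset of abundance values, and re-draws the species
identities uniformly *without replacement* from the whole pool.  This is
the literal reading of "keep each plot's species frequency, randomize
identities over the pool"; an alternative null that shuffles the tip labels
of the distance matrix is available via `null_model = "labels"`.  Both are
standard; the pool-draw null is the default because it matches the
description of the original procedure most directly.  Richer nulls
(independent swap, trial swap) are deliberately out of scope.

The standardized effect size per plot is
$\mathrm{SES} = (\mathrm{obs} - \bar x_{\mathrm{null}}) / s_{\mathrm{null}}$,
positive for overdispersion, negative for clustering (no NRI/NTI sign
flip).  `rank_p` is the two-sided permutation quantile with the add-one
correction.  Defaults: `n_null = 999`.  Degenerate cases are reported as
missing rather than guessed: plots with fewer than two species have no MPD,
and a null with zero standard deviation (e.g. richness equal to the pool
size under presence/absence) yields `NA` SES.

SES is invariant to rescaling all branch lengths by a positive constant
(numerator and denominator scale together), so the phylogeny's time units
never matter.

Habitat-level assemblages are the element-wise sums of their member plots'
abundance rows, analysed with exactly the same machinery — the two spatial
scales differ only in their units.

## Beta structure: Dpw, Dnn, spatial distances, Mantel tests

Between assemblages, `dpw()` is the mean patristic distance over all
ordered cross pairs, *including* the zero self-distances of shared species
(the convention of the standard between-community MPD; `exclude_shared`
drops them).  `dnn()` averages, in both directions, each species' minimum
distance into the other assemblage, and then averages the two directional
means; the symmetrization is a design choice — the directional version is
asymmetric and no direction is privileged here.  Note that some
implementations pool all nearest-neighbour distances into a single mean,
which differs from the average-of-means when richness differs.

`sesBeta()` applies the same pool-randomization null jointly to all units
per randomization and reports per-pair SES matrices (positive SES =
observed dissimilarity above the null expectation), plus the null moment
matrices for transparency.

Geographic distances are great-circle (haversine, Earth radius 6,371 km)
on latitude/longitude; with latitude only, the meridian arc is used.
Elevation distance is $|\Delta \mathrm{elevation}|$ in metres.

`mantelTest()` correlates the unfolded upper triangles (Pearson) and
permutes rows and columns of the second matrix simultaneously;
`partialMantelTest()` uses the first-order partial correlation and permutes
the first matrix, recomputing the partial statistic each time.  The default
alternative is one-sided "greater", since distance-decay hypotheses are
directional; `p = (1 + \#\{r^* \ge r\})/(n_{perm}+1)`.  At the habitat
scale the same machinery runs on (typically) four units — six pairs — so
the permutation p-value granularity is coarse (4! = 24 relabelings); this
is documented rather than hidden, and plot-scale tests carry the
inferential weight.

## Habitat delimitation: multivariate regression trees

The response is the whole plot-by-species matrix, by default untransformed
(a Hellinger transform is behind `hellinger = TRUE`).  Node impurity is the
sum of squared deviations from the node's multivariate mean; splits are
single-variable thresholds on numeric predictors (elevation, latitude,
optionally longitude), searched exhaustively over midpoints between
consecutive sorted unique values.  Ties are broken by predictor order as
configured, then by the smaller threshold, for reproducibility.  No
surrogate splits, categorical predictors or missing-value handling: the
survey design needs none of them.

The maximal tree (grown until `min_leaf` or zero impurity stops it) is
pruned by weakest-link cost-complexity pruning, giving a nested sequence of
subtrees with thresholds $\alpha_1 = 0 < \alpha_2 < \dots$.  The
cross-validated relative error of each size is

$$\mathrm{CVRE}(k) = \frac{\text{held-out prediction SS at size } k}
                          {\text{total SS about the grand mean}},$$

estimated by `cv_folds`-fold cross-validation repeated `n_cv_reps` times:
each training tree is pruned at the geometric means of the full-data
$\alpha$ sequence, and held-out plots are predicted by their training
leaf's species means.  The selected size *minimizes* mean CVRE (not the
1-SE rule — the minimum-CVRE rule is the one the analysis this package
systematizes states), with ties resolved towards the smaller tree.
Defaults: `min_leaf = 5`, `cv_folds = 10`, `n_cv_reps = 50` (fold
assignment is seeded; repeats average out fold-assignment noise).  On pure
noise CVRE hovers just above 1 for every split, so the root-only tree is
selected.  $R^2 = 1 - \text{resubstitution relative error}$ of the selected
tree.  Leaves become habitats `H1..Hk`, ordered by leaf-mean elevation then
latitude, so labels are stable across runs.

## Indicator species

For species $s$ and habitat $j$, specificity
$A_{sj} = \bar y_{sj} / \sum_{j'} \bar y_{sj'}$ (relative mean abundance),
fidelity $B_{sj}$ = fraction of $j$'s plots occupied, and
$\mathrm{IndVal}_{sj} = A_{sj} B_{sj}$ on the 0–1 scale (1 = present in
every plot of one habitat, absent elsewhere).  Significance of each
species' maximum-habitat statistic comes from permuting the plot-to-habitat
labels (group sizes preserved) — the classical convention; "randomizing
species occurrences" is read as this label permutation.  Raw permutation
p-values are reported by default (no multiplicity correction, matching
common practice for this analysis); Holm correction is behind a flag.
Species with zero total abundance are excluded from testing.

## The synthetic-community generator

Because the motivating survey's raw data are not deposited, validation
rests on simulated communities whose generating process is known.  The
generator emulates the survey design: by default 236 plots of 1 m² in four
elevation zones (1,200–1,500, 1,500–1,800, 1,800–2,000, 2,000–2,200 m) of
59 plots each, a latitude range of roughly 36.67–36.88° N split at its
midline (standing in for river barriers), 168 species, and four latent
habitat types.  The latent habitat rule mirrors the expected tree
structure: the lowest `n_habitats − 2` elevation bands are habitats on
their own, and the top two bands are split by the latitude midline.

Per-plot richness is Poisson (`mean_richness`, default 15, truncated below
at 2) and is drawn once per seed, identically across processes, so process
effects are never confounded with richness — richness is exactly what the
null model conditions on.  Abundances are 1 + geometric
(`abundance_mean`, default 3); the abundance distribution is a package
choice, as plot counts of individuals are typically strongly right-skewed
and no distribution is prescribed by the survey.

Assembly processes (combinable; weights multiply):

* **neutral** — uniform draws from the pool.
* **filtering** — Gaussian kernel on a Brownian tolerance trait about a
  plot optimum; kernel width `sd(trait)/(1 + strength)`.  By default the
  optimum maps plot elevation linearly into the trait range (a smooth
  gradient).  With `habitat_structure = TRUE` the optimum is the latent
  habitat's characteristic trait quantile instead — a step function of
  elevation band and latitude side, i.e. habitat specialization.  The step
  variant exists because a smooth compositional gradient has no true
  threshold structure for a regression tree to recover: habitat-recovery
  validation needs composition that actually changes at the habitat
  boundaries.  `filter_gradient` optionally relaxes filtering strength
  linearly with elevation.
* **limiting similarity** — sequential admission; a candidate is rejected
  when its patristic distance to any resident falls below the
  `0.8·strength/(1+strength)` quantile of pool distances.  When no
  candidate complies, the most distant one is admitted and a single warning
  summarizes how often this fallback fired — the requested richness is
  honoured rather than silently reduced.
* **dispersal limitation** — each species has a Gaussian range kernel
  about a uniform random centre; the kernel scale is the regional extent
  divided by `2(1 + strength)`.

What the generator does *not* emulate: real abundance structure
(zero-inflation, dominance), spatially autocorrelated environments beyond
the elevation zones, climate (only the implicit linear
elevation–temperature proxy), grazing, hydrology, or interactions between
processes and richness.  Passing tests therefore demonstrate correctness
and calibration of the statistical machinery under known processes — not
that any particular field system behaves like the simulations.

One empirical caveat found during validation and worth stating: under
trait-kernel filtering with a Brownian (conserved) trait, a minority of
plots receive optima in trait regions where distant clades converge, so
even strong filtering leaves roughly 10–20% of plots without phylogenetic
clustering.  Dataset-level clustering (mean SES.mpd well below zero) is
robust; per-plot universality is not, and the tests are phrased
accordingly.

## Reproducibility and numerics

Every stochastic stage takes an explicit integer seed; `runPipeline()`
derives one child seed per stage from the master seed via a deterministic
hash (`childSeed()`), so a single integer reproduces a whole run and
changing one stage's settings leaves the other streams untouched.  The RNG
state of the caller is never clobbered.  Identical configurations produce
byte-identical output tables; the run directory carries the verbatim
configuration, a timestamped log, and an md5 manifest of every output.

Floating-point ties in the split search are resolved with a $10^{-12}$
tolerance in favour of the incumbent (earlier predictor, smaller
threshold).  Permutation p-values always use the add-one correction and so
lie in $(0, 1]$.  Means and standard deviations of null distributions are
accumulated in one pass; SES is reported missing when the null sd is zero.

## Problem sizes used by the test suite

The validation suite runs at desk scale, chosen once as realistic for this
kind of survey: oracle checks on 200 random 4–10-tip instances per metric;
null calibration on 200 neutral plots over a 100-species pool with 999
randomizations; process-recovery checks on ten replicate 60-plot datasets
(199 randomizations each); habitat recovery on ten replicate 160-plot,
60-species scenarios with 10-fold cross-validation repeated 3 times;
Mantel calibration on 1,000 pairs of independent 50-unit matrices with 199
permutations, and power on ten replicate 30-plot dispersal-limitation
datasets.  Package defaults (e.g. `n_null = 999`, `n_cv_reps = 50`) remain
the recommended analysis settings.

## Known limitations

* The MRT handles numeric predictors only; no surrogate splits.
* Only the pool-draw and label-shuffle nulls are provided.
* No UniFrac/PhyloSor-family beta metrics, Moran's I, or eigenvector-based
  spatial partitioning — Mantel/partial Mantel is the scope boundary.
* Habitat-scale permutation tests on four units are granular; treat them as
  descriptive alongside the plot-scale tests.
* Reported regressions of SES on gradients are single-predictor OLS; the
  package reports slope, $R^2$ and p rather than claiming any one of them
  is "the" statistic of record.
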