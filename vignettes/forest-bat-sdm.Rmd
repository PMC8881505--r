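---
title: "Modelling forest-structure drivers of species distributions with forestsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling forest-structure drivers of species distributions with forestsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestsdm)
```

## The problem

Forest specialists — the motivating case is forest bats in Mediterranean
regions — may respond to the structure and composition of forest stands not
only in their local habitat use but in where they occur at regional scale.
Quantifying this requires joining three data streams: a forest inventory
(trees measured on small circular plots laid out on a regular grid),
presence-only occurrence records, and climatic/topographic rasters. The
`forestsdm` pipeline covers the whole chain:

1. **Plot variables.** Per-plot structural and compositional metrics from
   tree records: stem densities (total, dead, large-tree, softwood
   large-tree), mean and range of diameter at breast height (DBH) and
   height, species richness, basal area, basal-area-weighted wood density,
   and the dominant species by basal area. The inventory convention is
   followed throughout: trees enter above 75 mm DBH, plots are 25 m in
   diameter (area 490.874 m^2, so one stem is 20.37 stems/ha), and 425 mm
   DBH marks "large" trees.
2. **Home-range-scaled interpolation.** Occurrence records are un-clustered
   (spatial thinning), then each point receives the mean (quantitative) or
   mode (categorical) of the nearest *k* plots within a maximum distance,
   both scaled to the species' home range: less-mobile species use 2–5
   plots within 3 km and 500 m thinning, intermediate species 4–8 plots
   within 5 km and 1 km thinning, mobile species 8–16 plots within 7 km and
   2 km thinning.
3. **Background generation.** An initial uniform draw over the region
   (10,000 points by default) thinned at 4–5 km; plots closer than the
   exclusion buffer (4–5 km) to any presence leave the background
   interpolation pool, so background environments never describe presence
   neighbourhoods.
4. **Maxent.** A from-scratch presence–background maximum-entropy model
   (below), tuned over feature classes L/LQ/H/LQH and regularization
   multipliers 1–3 by AICc, evaluated by 6-fold cross-validated AUC.
5. **Null models.** The observed test AUC is compared to replicate runs of
   the identical pipeline on uniformly random presence sets of the same
   size; a model is "better than random" when its AUC exceeds the null 95th
   percentile (type-7 empirical quantile).
6. **Trait meta-analysis.** Per-species training gains — total, per
   mechanistic variable group (roost availability, structural
   heterogeneity, clutter, composition, climate, forest proportion), and
   per variable — are related to roosting ecology (two-group ANOVA) and to
   wing loading and aspect ratio (linear models with the record count as a
   covariate), with Holm correction across families of tests.

## The Maxent model

The model is a Gibbs density over the background sample,
$q(x) = \exp(\beta^\top f(x)) / Z$ with $Z = \sum_{b} \exp(\beta^\top f(x_b))$,
fitted by minimizing the regularized negative log-likelihood of the
presences

$$O(\beta) \;=\; -\tfrac1n \sum_i \beta^\top f(x_i) \;+\; \log Z \;+\;
\sum_j \lambda_j |\beta_j|.$$

Features are scaled to $[0,1]$ on the background: linear (min–max scaled
value), quadratic (scaled square), hinge in both directions with 50 knots
per direction at background quantiles (duplicates dropped, knots strictly
inside the range), and one indicator per level of categorical variables.
Per-feature penalties follow the published Maxent defaults,
$\lambda_j = \mathrm{rm}\cdot\beta_{class}(n)\cdot s_j/\sqrt n$, where
$s_j$ is the feature's standard deviation over the presences (floored at
0.05 so presence-constant features keep a positive penalty), the class base
value is 0.5 for hinge features and interpolated over sample size for
linear/quadratic and categorical features, and rm is the global multiplier.

Optimization is cyclic coordinate descent (compiled): each coordinate
subproblem is solved exactly — a soft-threshold test at zero, then a
safeguarded Newton/bisection search for the root of
$E_q[f_j] = E_{pres}[f_j] - \lambda_j\,\mathrm{sign}(\beta_j)$. Convergence
is declared only when a full pass confirms the defining Kuhn–Tucker
property $|E_{pres}[f_j]-E_q[f_j]| \le \lambda_j$ (with equality for active
features) within $10^{-6}$; the test suite asserts this on every model it
fits, together with the closed-form solution $\beta=\ln 19$ for a single
binary feature at $\lambda = 0.05$.

By default the pipeline adds the presence samples to the background before
fitting (the standard Maxent convention). This matters here: because the
exclusion buffer removes presence-neighbourhood plots from the background
pool, interpolated presences can lie outside the sampled background range,
and without the added samples the likelihood is quasi-separable and
coefficients diverge.

**Training gain** is $G = \tfrac1n\sum_i \log q(x_i) + \log N_{bg}$, the
mean log improvement over a uniform background density; it is 0 for the
null model and non-negative at the optimum. **Variable contributions** use
path attribution: every coordinate update's objective improvement is
credited to the variable owning the updated feature, positive credits are
normalized to sum to $G$. Like Maxent's own "percent contribution" this is
path-dependent for strongly correlated variables — an exact duplicate pair
splits its joint credit by visiting order, symmetric only across randomized
orders (`path_seed`); permutation importance is provided as an
order-independent cross-check. **AICc** is $2k - 2\ell\ell + 2k(k+1)/(n-k-1)$
with $k$ the number of non-zero coefficients and $\ell\ell$ the summed log
raw output at presences; models with $n \le k+1$ are disqualified from
tuning. AUC is the rank-based (Mann–Whitney) probability that a presence
outscores a background point, ties counted half.

## The synthetic-data module

`generate_landscape()` emulates the statistical structure the analysis
assumes, not any particular geography:

- a binary forest mask produced by thresholding a smooth random field at
  the configured forest fraction, with inventory plots on the regular 1-km
  grid restricted to forested cells;
- climate surfaces as sums of low-frequency cosine bases — cheap, seedable,
  and with controlled marginal mean/SD and spatial length scale (a
  Gaussian-process draw would be statistically richer but is unnecessary
  for smooth regional gradients);
- a two-component truncated-lognormal DBH mixture: dense "young" stands
  (all stems 75–425 mm) and "mature" stands in which a configurable
  fraction of stems exceeds 425 mm. Lognormal DBH is standard forestry
  practice; the two components mirror the contrast between widespread young
  planted Mediterranean stands and scarce mature ones. Mature stands are
  spatially clustered (a thresholded smooth field with plot-level noise),
  as real mature forest is — this also means landscape-scale interpolation
  preserves the structural signal;
- virtual species whose occurrence probability is the logistic link of
  centred response terms (linear, saturating, or upper-quartile threshold)
  in any plot variable, sampled proportionally to suitability and jittered
  within 300 m of the source plot (occurrence records are capture sites
  offset from the habitat they represent; the real records' stated
  precision is finer, under 50 m, but the capture-site offset dominates).

What the generator does *not* emulate: nested-radius plot designs,
geodesic coordinates, observation bias by sampling method, temporal
structure, and species interactions. Passing the recovery tests therefore
shows the pipeline correctly extracts the relationships it assumes — not
that those assumptions hold in any particular real data set.

The bundled study (`demo_species_set()`, `demo_spatial_params()`,
`demo_landscape_config()`) is a nine-species virtual community on a
60 x 60 km landscape with 70% forest: four tree-roosting species driven by
large-tree and softwood large-tree densities and five non-tree-roosting
species driven by climate gradients, with home-range classes and synthetic
trait values mirroring the structure of a real Mediterranean assemblage
(tree-roosters have higher wing loading; the two most mobile species are
open-space foragers). Response coefficients are set to strong effects
(4–5 standard deviations on the linear predictor for the primary driver) so
that recovery is expected, which is the point of a positive control.

## Numerical and design choices

- **Thinning.** The un-clustering algorithm is greedy maximum-neighbour
  elimination with seeded random tie-breaks: while any pair is closer than
  the minimum distance, remove the point with most neighbours. This is the
  single biggest procedural gap the pipeline had to fill — the source
  procedure is not specified beyond "un-clustering" — and the spThin-style
  greedy rule is the field's standard.
- **Interpolation drops.** A point with fewer than `k_min` plots within the
  maximum distance is dropped and logged, never imputed; presences and
  backgrounds obey the same rule. Thinning runs before interpolation.
- **Mode ties** in categorical interpolation go to the nearest plot's
  value; dominant-species ties within a plot go to the lexicographically
  smallest code. Both make reruns bit-identical.
- **Wood density** is averaged weighted by basal area, the forestry
  convention for stand-level wood properties.
- **Region size.** Examples and tests run on 24–60 km synthetic regions
  with background thinning scaled accordingly (2–5 km), sized so thinned
  backgrounds hold one to two hundred points; the method itself is
  indifferent to extent.
- **Null-model percentiles.** With few null replicates the type-7 95th
  percentile sits close to the null maximum and the "better than random"
  verdict fires slightly too often; calibration experiments therefore use
  at least 30 nulls per replicate, and the package default is 100, at
  which the empirical percentile is stable.
- **Cross-validation** partitions presences randomly into 6 folds, reusing
  the full background in every fold (standard presence-background
  practice); the reported test AUC is the mean over folds.
- **Tie-breaks in tuning** go to the larger regularization multiplier,
  then to the shorter feature-class string — the more parsimonious model.
- **Seeds.** A master seed fans out to stage- and species-tagged sub-seeds
  through a stable polynomial hash (`derive_seed`), so adding a species
  never perturbs another species' stream, and identical configurations
  reproduce byte-identical outputs.
- **Degenerate inputs.** Zero-variance variables are excluded from feature
  expansion with a warning; an all-zero suitability surface, an empty
  background after exclusion, and a tuning grid with no valid AICc are
  errors, not silent results. A two-group ANOVA with zero within-group
  variance reports an overflow flag rather than an infinite statistic.

## Trait-level inference

`anova_two_group()` (raw values) and `anova_from_summary()` (printed group
means/SDs/sizes) implement the same one-way two-group ANOVA and agree to
1e-10 on exact summaries; the latter exists so published summary tables can
be re-analysed without raw data. `lm_gain_on_trait()` reports the overall
F, R^2 and the trait's partial p from `response ~ trait + n_records`.
Wing-morphology tests are restricted to within-forest foragers
(`forager_class`), since flight-morphology constraints on clutter use do
not apply to species foraging in open space above the canopy. Gains enter
untransformed. Holm correction is applied across each family of per-variable
tests.

## Limitations

- Planar Euclidean distances only; project coordinates to metres first.
- The null models randomize presence locations uniformly (optionally
  within forest); they do not preserve the spatial clustering of real
  records, so their significance statements share that known optimism.
- Path attribution of gain is order-dependent among strongly correlated
  variables; use `permutation_importance()` alongside it.
- No product or threshold Maxent features, and no cloglog output
  calibration; raw output only.
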