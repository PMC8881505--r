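# forestsdm

Tools for asking how much forest *structure and composition* — as opposed to
climate — drive the regional-scale distributions of forest specialists, with
forest bats as the motivating system. The package implements the full chain
from forest-inventory tree records to trait-level inference:

- **Plot variables** from inventory tree records (25-m-diameter plots on a
  1-km grid, stems above 75 mm DBH): stem densities, large-tree (DBH >
  425 mm) and softwood large-tree densities, dead-tree density, DBH/height
  means and ranges, species richness, basal area, basal-area-weighted wood
  density, dominant species.
- **Home-range-scaled interpolation**: occurrence records are spatially
  thinned, then each point receives the mean/mode of the nearest *k* forest
  plots within a species-specific distance (2–5 plots within 3 km for
  less-mobile species, up to 8–16 within 7 km for mobile ones).
- **Background generation** with per-species thinning (4–5 km) and removal
  of plots within an exclusion buffer of any presence.
- **Maxent, from scratch**: an L1-regularized maximum-entropy
  presence–background model with linear, quadratic and hinge features,
  published default penalties, exact coordinate-wise optimization (compiled)
  with verified KKT optimality, training gain, path-attributed per-variable
  contributions, permutation importance, rank-based AUC, AICc, and a
  feature-class x regularization tuning grid.
- **Null-model calibration**: the observed cross-validated test AUC is
  compared against replicate runs of the identical pipeline on random
  presence sets ("better than random" above the null 95th percentile).
- **Trait meta-analysis**: two-group ANOVAs (from raw values or from printed
  group summaries), linear models with a record-count covariate, and Holm
  correction relate per-species gains to roosting ecology, wing loading and
  aspect ratio.
- **Synthetic data**: seedable generators for forest landscapes, tree
  tables, climate surfaces (ESRI ASCII grid I/O) and virtual species, plus a
  bundled nine-species virtual bat community used as a positive control.

The model at the core is the Gibbs density `q(x) = exp(beta . f(x)) / Z`
over background points, fitted by minimizing
`-(1/n) sum_i beta.f(x_i) + log Z + sum_j lambda_j |beta_j|`;
training gain `G = (1/n) sum_i log q(x_i) + log N_bg` is the currency in
which variable importance and trait effects are expressed.

## Worked example

```r
library(forestsdm)

## a 24-km synthetic landscape, one tree-roosting virtual species
cfg <- landscape_config(extent_km = 24, forest_fraction = 0.8, seed = 42)
ls  <- generate_landscape(cfg)
pv  <- extract_climate_to_plots(compute_plot_variables(ls$plots, ls$trees),
                                ls$climate)
sp  <- virtual_species("demo", "tree",
         response_terms = list(list(variable = "large_tree_density",
                                    form = "linear", coef = 4)),
         n_occurrences = 50)
occ <- sample_occurrences(sp, pv, seed = 42)

par <- spatial_params("less-mobile", thin_background_km = 2, exclusion_km = 2)
fit <- fit_species_sdm(occ, pv, par,
                       model_settings(classes = "LQ", n_bg_init = 2000,
                                      n_bg_max = 200),
                       region = c(0, 24000, 0, 24000),
                       forest_prop = forest_proportion_layer(ls$landcover),
                       seed = 42)
round(c(gain = fit$gain, auc_test = fit$auc_test), 3)
#>     gain auc_test
#>    0.617    0.656
round(fit$contrib$group, 3)
#>            climate            clutter        composition  forest_proportion
#>              0.101              0.079              0.088              0.010
#>      heterogeneity roost_availability
#>              0.009              0.330
```

The fitted model recovers the generating structure: the largest share of
the training gain (0.33 of 0.62) is credited to the roost-availability
variable group that contains `large_tree_density`, and the model
discriminates presences from background (test AUC 0.66 on a deliberately
small example). `run_pipeline()` wraps the same steps for a whole
species community and finishes with the trait-level tests; see the
vignette in `vignettes/forest-bat-sdm.Rmd` for the model, its assumptions
and the design choices.

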