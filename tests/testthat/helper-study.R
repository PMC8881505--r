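## Shared fixtures: landscapes are expensive, so they are generated once per
## test run and cached. All fixtures are built in code, none stored on disk.

study_cache <- new.env(parent = emptyenv())

## the bundled 60-km demo study landscape with derived plot variables
study_landscape <- function(seed = 7) {
  key <- paste0("demo", seed)
  if (is.null(study_cache[[key]])) {
    ls <- generate_landscape(demo_landscape_config(seed = seed))
    pv <- extract_climate_to_plots(
      compute_plot_variables(ls$plots, ls$trees), ls$climate)
    pv <- pv[pv$climate_complete, , drop = FALSE]
    study_cache[[key]] <- list(
      landscape = ls, pv = pv,
      fprop = forest_proportion_layer(ls$landcover),
      region = c(0, 60000, 0, 60000))
  }
  study_cache[[key]]
}

## a smaller 30-km landscape used for the null-model calibration experiment
calib_landscape <- function(seed = 21) {
  key <- paste0("calib", seed)
  if (is.null(study_cache[[key]])) {
    cfg <- landscape_config(extent_km = 30, forest_fraction = 0.7, seed = seed)
    ls <- generate_landscape(cfg)
    pv <- extract_climate_to_plots(
      compute_plot_variables(ls$plots, ls$trees), ls$climate)
    pv <- pv[pv$climate_complete, , drop = FALSE]
    study_cache[[key]] <- list(
      landscape = ls, pv = pv,
      fprop = forest_proportion_layer(ls$landcover),
      region = c(0, 30000, 0, 30000))
  }
  study_cache[[key]]
}

## spatial/model settings for the calibration experiment: a reduced variable
## set and thinning distances scaled to the 30-km region
calib_params <- function() {
  spatial_params("less-mobile", thin_background_km = 2, exclusion_km = 2)
}

calib_settings <- function() {
  model_settings(
    variables = c("large_tree_density", "softwood_large_density",
                  "tree_density", "dbh_range", "elevation", "annual_precip"),
    categorical = character(0), classes = "LQ", rm = 1,
    n_bg_init = 2000, n_bg_max = 200, nfolds = 6)
}

## small random feature problems for maxent property tests
random_feature_problem <- function(seed, n_pres = 30, n_bg = 80, n_vars = 3) {
  set.seed(seed)
  mk <- function(n) {
    d <- as.data.frame(matrix(stats::rnorm(n * n_vars), n, n_vars))
    names(d) <- paste0("v", seq_len(n_vars))
    d
  }
  pres <- mk(n_pres)
  pres$v1 <- pres$v1 + 1          # shift so the problem is informative
  list(pres = pres, bg = mk(n_bg))
}

## random plot tables for interpolation / plot-variable oracles
random_plot_table <- function(seed, n = 30, extent = 5000) {
  set.seed(seed)
  data.frame(
    plot_id = sprintf("R%03d", seq_len(n)),
    x_m = stats::runif(n, 0, extent), y_m = stats::runif(n, 0, extent),
    a = stats::rnorm(n), b = stats::runif(n, 0, 100),
    cat1 = sample(c("u", "v", "w"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

expect_kkt <- function(model, fe, tol = 1e-6, active_tol = 1e-3) {
  k <- kkt_check(model, fe)
  expect_lte(k$max_violation, tol)
  if (any(model$beta != 0)) expect_lte(k$max_active_gap, active_tol)
  invisible(k)
}
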