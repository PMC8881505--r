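## End-to-end orchestration: synthetic landscape -> plot variables ->
## thinning -> interpolation -> background -> Maxent tuning/fit ->
## evaluation -> null models -> species gain profiles -> trait tests.
## The master seed fans out to per-stage, per-species seeds through
## derive_seed(), so adding a species never perturbs another's results.

#' Model-stage settings
#'
#' @param variables quantitative variable names to model; defaults to the
#'   quantitative entries of [variable_catalog()] except `forest_proportion`
#'   (always appended when a proportion layer is available).
#' @param categorical categorical variable names (default
#'   `dominant_species`, `development_stage`).
#' @param tune run the AICc tuning grid; otherwise fit the single setting
#'   `classes`/`rm`.
#' @param classes,rm fixed setting used when `tune = FALSE`.
#' @param classes_grid,rm_grid tuning grids.
#' @param n_hinge_knots hinge knots per direction.
#' @param nfolds cross-validation folds (default 6).
#' @param n_bg_init initial random background points (default 10000).
#' @param n_bg_max optional cap on background samples.
#' @return list of settings.
#' @export
model_settings <- function(variables = NULL, categorical = NULL, tune = FALSE,
                           classes = "LQ", rm = 1,
                           classes_grid = c("L", "LQ", "H", "LQH"),
                           rm_grid = c(1, 1.5, 2, 2.5, 3),
                           n_hinge_knots = 50, nfolds = 6,
                           n_bg_init = 10000, n_bg_max = NULL) {
  cat_tab <- variable_catalog()
  quant <- cat_tab$variable[cat_tab$type == "quantitative" &
                              cat_tab$group != "forest_proportion"]
  list(variables = variables %||% quant,
       categorical = categorical %||% c("dominant_species", "development_stage"),
       tune = tune, classes = classes, rm = rm, classes_grid = classes_grid,
       rm_grid = rm_grid, n_hinge_knots = n_hinge_knots, nfolds = nfolds,
       n_bg_init = n_bg_init, n_bg_max = n_bg_max)
}

#' Fit the full per-species SDM procedure for a given presence point set
#'
#' The species-level unit of the pipeline, also used verbatim for null
#' replicates: un-cluster the presences, interpolate plot variables (and the
#' forest-proportion layer) to them, generate and interpolate background
#' points with presence-plot exclusion, fit (or tune) the Maxent model, and
#' evaluate cross-validated test AUC and per-variable gain contributions.
#'
#' @param presences_xy data frame of raw presence points (`x_m`, `y_m`).
#' @param plot_vars plot-variables table with climate columns attached.
#' @param params a [spatial_params()].
#' @param settings a [model_settings()].
#' @param region extent `c(xmin, xmax, ymin, ymax)` (m).
#' @param forest_prop optional forest-proportion [grid_raster()].
#' @param catalog a [variable_catalog()]-style table.
#' @param seed integer seed.
#' @return list: `model`, `auc_test`, `auc_train`, `gain`, `contrib`
#'   (variable/group), `tuning` (grid report or NULL), `presences`,
#'   `background` (EnvSample tables), `n_presences_used`, `n_dropped`.
#' @export
fit_species_sdm <- function(presences_xy, plot_vars, params, settings, region,
                            forest_prop = NULL, catalog = variable_catalog(),
                            seed = 1L) {
  thin <- thin_points(presences_xy, params$thin_presence_m,
                      seed = derive_seed(seed, "presence-thin"))
  quant <- intersect(settings$variables, names(plot_vars))
  categ <- intersect(settings$categorical, names(plot_vars))
  if (!length(quant)) stop_fsd("no quantitative model variables found in plot table")
  ip <- interpolate_to_points(thin, plot_vars, params, quant, categ,
                              label = "presence")
  pres <- ip$samples
  if (nrow(pres) < 4)
    stop_fsd("too few presences after thinning/interpolation (%d)", nrow(pres))
  bg <- generate_background(region, pres, plot_vars, params, quant, categ,
                            n_init = settings$n_bg_init,
                            n_max = settings$n_bg_max,
                            seed = derive_seed(seed, "background"))
  vars <- quant
  if (!is.null(forest_prop)) {
    pres$forest_proportion <- raster_extract(forest_prop, pres$x_m, pres$y_m)
    bg$samples$forest_proportion <- raster_extract(forest_prop, bg$samples$x_m,
                                                   bg$samples$y_m)
    vars <- c(vars, "forest_proportion")
  }
  all_vars <- c(vars, categ)
  tuning <- NULL
  if (isTRUE(settings$tune)) {
    tn <- tune_maxent(pres, bg$samples, vars = all_vars,
                      classes_grid = settings$classes_grid,
                      rm_grid = settings$rm_grid,
                      n_hinge_knots = settings$n_hinge_knots,
                      nfolds = settings$nfolds,
                      seed = derive_seed(seed, "cv"),
                      add_samples_to_background = TRUE)
    model <- tn$best_model
    cv <- tn$cv
    tuning <- tn$grid
  } else {
    fe <- expand_features(pres, bg$samples, vars = all_vars,
                          classes = settings$classes,
                          n_hinge_knots = settings$n_hinge_knots,
                          add_samples_to_background = TRUE)
    model <- maxent_fit(fe, rm = settings$rm)
    cv <- cv_auc(fe, rm = settings$rm, nfolds = settings$nfolds,
                 seed = derive_seed(seed, "cv"))
  }
  contrib <- variable_contribution(model, catalog = catalog)
  list(model = model, auc_test = cv$auc_test_mean, auc_train = cv$auc_train,
       auc_test_folds = cv$auc_test_folds, gain = model$gain, contrib = contrib,
       tuning = tuning, presences = pres, background = bg$samples,
       n_presences_used = nrow(pres), n_dropped = nrow(ip$dropped))
}

#' Pipeline configuration
#'
#' @param landscape a [landscape_config()].
#' @param species list of [virtual_species()].
#' @param spatial named list of [spatial_params()], one per species name.
#' @param settings a [model_settings()].
#' @param nulls list(`enabled`, `n_reps`); null models per species.
#' @param seed master seed.
#' @param outdir optional output directory for persisted CSV/JSON stage
#'   outputs.
#' @return validated configuration of class `pipeline_config`.
#' @export
pipeline_config <- function(landscape, species, spatial,
                            settings = model_settings(),
                            nulls = list(enabled = FALSE, n_reps = 100),
                            seed = 1L, outdir = NULL) {
  stopifnot(inherits(landscape, "landscape_config"))
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop_fsd("validation error: duplicated species names")
  missing_sp <- setdiff(nm, names(spatial))
  if (length(missing_sp))
    stop_fsd("validation error: species lacking spatial params: %s",
             paste(missing_sp, collapse = ", "))
  for (s in species) stopifnot(inherits(s, "virtual_species"))
  for (p in spatial) stopifnot(inherits(p, "species_spatial_params"))
  structure(list(landscape = landscape, species = species, spatial = spatial,
                 settings = settings, nulls = nulls, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: landscape generation, plot variables + climate extraction,
#' forest-proportion layer, then per species: occurrence simulation,
#' thinning, interpolation, background, model fit/tuning, evaluation and
#' (optionally) null models; finally gain profiles and trait tests. All
#' stages are seeded deterministically from the master seed.
#'
#' @param config a [pipeline_config()].
#' @return list: `profiles` (per-species gain profile table), `species`
#'   (per-species fit results), `trait_tests` (tidy results table),
#'   `plot_vars`, `landscape`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ls <- generate_landscape(config$landscape)
  pv <- compute_plot_variables(ls$plots, ls$trees,
                               plot_diameter_m = config$landscape$plot_diameter_m)
  pv <- extract_climate_to_plots(pv, ls$climate)
  pv <- pv[pv$climate_complete, , drop = FALSE]
  fprop <- forest_proportion_layer(ls$landcover, fact = 25)
  ext <- config$landscape$extent_km * 1000
  region <- c(0, ext, 0, ext)
  catalog <- variable_catalog()

  species_out <- list()
  profile_rows <- list()
  for (sp in config$species) {
    sp_seed <- derive_seed(config$seed, paste0("species/", sp$name))
    occ <- sample_occurrences(sp, pv, seed = sp_seed)
    fit <- fit_species_sdm(occ, pv, config$spatial[[sp$name]], config$settings,
                           region, forest_prop = fprop, catalog = catalog,
                           seed = sp_seed)
    nulls <- NULL
    if (isTRUE(config$nulls$enabled)) {
      pfn <- function(pts, seed) {
        fit_species_sdm(pts, pv, config$spatial[[sp$name]], config$settings,
                        region, forest_prop = fprop, catalog = catalog,
                        seed = seed)
      }
      nulls <- run_null_models(pfn, n_presences = nrow(occ), region = region,
                               observed_auc = fit$auc_test,
                               n_reps = config$nulls$n_reps %||% 100,
                               seed = derive_seed(config$seed,
                                                  paste0("nulls/", sp$name)))
    }
    g_grp <- fit$contrib$group
    grp_val <- function(g) if (g %in% names(g_grp)) unname(g_grp[g]) else 0
    forest_gain <- sum(vapply(c("roost_availability", "heterogeneity",
                                "clutter", "composition"), grp_val, numeric(1)))
    profile_rows[[sp$name]] <- data.frame(
      species = sp$name, n_records = fit$n_presences_used,
      gain = fit$gain, auc_test = fit$auc_test,
      gain_forest = forest_gain,
      gain_roost_availability = grp_val("roost_availability"),
      gain_heterogeneity = grp_val("heterogeneity"),
      gain_clutter = grp_val("clutter"),
      gain_composition = grp_val("composition"),
      gain_climate = grp_val("climate"),
      gain_forest_proportion = grp_val("forest_proportion"),
      roosting = sp$roosting, wing_loading = sp$wing_loading,
      aspect_ratio = sp$aspect_ratio, forager_class = sp$forager_class,
      better_than_random = if (is.null(nulls)) NA else nulls$better_than_random,
      stringsAsFactors = FALSE
    )
    species_out[[sp$name]] <- c(fit, list(nulls = nulls, occurrences = occ))
  }
  profiles <- do.call(rbind, profile_rows)
  rownames(profiles) <- NULL

  trait_tests <- NULL
  if (nrow(profiles) >= 4 && length(unique(profiles$roosting)) == 2 &&
      all(table(profiles$roosting) >= 2)) {
    tests <- list(
      anova_two_group(profiles$gain_forest, profiles$roosting,
                      "summed forest gain ~ roosting"),
      anova_two_group(profiles$gain_roost_availability, profiles$roosting,
                      "roost-availability gain ~ roosting"),
      anova_two_group(profiles$gain_forest_proportion, profiles$roosting,
                      "forest-proportion gain ~ roosting")
    )
    if (nrow(profiles) >= 5)
      tests <- c(tests, list(
        lm_gain_on_trait(profiles, "gain", "roosting"),
        lm_gain_on_trait(profiles, "gain_forest", "wing_loading"),
        lm_gain_on_trait(profiles, "gain_forest", "aspect_ratio")))
    trait_tests <- trait_results_table(tests)
  }

  manifest <- list(
    seed = config$seed, n_plots = nrow(pv),
    n_species = length(config$species),
    species = vapply(config$species, function(s) s$name, character(1)),
    n_records = profiles$n_records,
    generated = "run_pipeline"
  )
  out <- list(profiles = profiles, species = species_out,
              trait_tests = trait_tests, plot_vars = pv, landscape = ls,
              forest_proportion = fprop, manifest = manifest)
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

#' Persist pipeline outputs as plain-text files
#'
#' Writes the plot-variables table, per-species EnvSample tables, serialized
#' models, the gain-profile table, trait-test results and a JSON manifest.
#'
#' @param result a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$plot_vars, file.path(outdir, "plot_variables.csv"),
                   row.names = FALSE)
  utils::write.csv(result$profiles, file.path(outdir, "species_gain_profiles.csv"),
                   row.names = FALSE)
  if (!is.null(result$trait_tests))
    utils::write.csv(result$trait_tests, file.path(outdir, "trait_tests.csv"),
                     row.names = FALSE)
  for (nm in names(result$species)) {
    sp <- result$species[[nm]]
    utils::write.csv(rbind(sp$presences, sp$background),
                     file.path(outdir, sprintf("env_samples_%s.csv", nm)),
                     row.names = FALSE)
    maxent_to_json(sp$model, file.path(outdir, sprintf("model_%s.json", nm)))
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
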