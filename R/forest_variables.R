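## Plot-level structural and compositional variables derived from tree
## records, climate extraction to plots, and variable screening.

#' Default variable catalog
#'
#' Maps each modelled variable to its type and mechanistic group. Groups
#' follow the ecological rationale of the analysis: roost availability
#' (tree size/age and dead wood), structural heterogeneity, forest clutter,
#' composition, climate, and the landscape forest-proportion layer. The seven
#' roost-availability variables are mean tree DBH, mean tree height, dead
#' tree density, large-tree (>425 mm) density, softwood large-tree density,
#' development stage and basal-area-weighted wood density.
#'
#' @return data.frame with columns `variable`, `type`
#'   (`"quantitative"`/`"categorical"`), `group`.
#' @export
variable_catalog <- function() {
  rbind(
    data.frame(variable = c("tree_dbh_mean", "tree_height_mean", "dead_tree_density",
                            "large_tree_density", "softwood_large_density",
                            "development_stage", "wood_density_mean"),
               type = c(rep("quantitative", 5), "categorical", "quantitative"),
               group = "roost_availability", stringsAsFactors = FALSE),
    data.frame(variable = c("dbh_range", "height_range", "basal_area"),
               type = "quantitative", group = "heterogeneity", stringsAsFactors = FALSE),
    data.frame(variable = c("tree_density", "tree_cover", "understory_cover"),
               type = "quantitative", group = "clutter", stringsAsFactors = FALSE),
    data.frame(variable = c("dominant_species", "tree_richness", "plantation_pct"),
               type = c("categorical", "quantitative", "quantitative"),
               group = "composition", stringsAsFactors = FALSE),
    data.frame(variable = c("elevation", "annual_precip", "tmax_warmest",
                            "temp_seasonality"),
               type = "quantitative", group = "climate", stringsAsFactors = FALSE),
    data.frame(variable = "forest_proportion", type = "quantitative",
               group = "forest_proportion", stringsAsFactors = FALSE)
  )
}

#' Area of a circular inventory plot
#' @param diameter_m plot diameter in metres (default 25).
#' @return Area in m^2 (490.874 m^2 for the default).
#' @export
plot_area_m2 <- function(diameter_m = 25) pi * (diameter_m / 2)^2

#' Compute plot-level structural and compositional variables
#'
#' Derives, for every plot, per-hectare stem densities (total, dead,
#' large-tree with DBH > 425 mm, softwood large-tree), mean and range of DBH
#' and height, species richness, basal area, basal-area-weighted mean wood
#' density, and the dominant species (largest summed basal area; ties broken
#' by the lexicographically smallest code). Structural metrics are computed
#' over live stems; dead stems contribute only to `dead_tree_density`.
#' Plots without trees get zero densities, richness 0 and dominant species
#' `"none"`. Plot-level covariates carried in `plots` (`tree_cover`,
#' `understory_cover`, `plantation_pct`, `development_stage`) pass through.
#'
#' @param plots plot table (`plot_id`, `x_m`, `y_m`, plus carried covariates).
#' @param trees tree table (`plot_id`, `species_code`, `dbh_mm`, `height_m`,
#'   `status`, `wood`, `wood_density_g_cm3`).
#' @param plot_diameter_m plot diameter (m); densities scale by
#'   `10000 / plot_area_m2(plot_diameter_m)`.
#' @param large_dbh_mm large-tree threshold, default 425.
#' @return data.frame of plot variables, one row per plot.
#' @export
compute_plot_variables <- function(plots, trees, plot_diameter_m = 25,
                                   large_dbh_mm = 425) {
  stopifnot(all(c("plot_id", "x_m", "y_m") %in% names(plots)))
  if (nrow(trees) > 0) {
    bad <- trees$dbh_mm <= 0 | trees$height_m <= 0 |
      !is.finite(trees$dbh_mm) | !is.finite(trees$height_m)
    if (any(bad))
      stop_fsd("data error: non-positive DBH/height in plot(s) %s",
               paste(unique(trees$plot_id[bad]), collapse = ", "))
  }
  per_ha <- 10000 / plot_area_m2(plot_diameter_m)
  ba_m2 <- function(dbh_mm) pi * (dbh_mm / 2000)^2   # stem basal area, m^2

  out <- plots
  zero <- rep(0, nrow(plots))
  out$tree_dbh_mean <- out$tree_height_mean <- zero
  out$dbh_range <- out$height_range <- zero
  out$tree_density <- out$large_tree_density <- zero
  out$softwood_large_density <- out$dead_tree_density <- zero
  out$tree_richness <- zero
  out$basal_area <- out$wood_density_mean <- zero
  out$dominant_species <- rep("none", nrow(plots))

  if (nrow(trees) > 0) {
    split_trees <- split(trees, factor(trees$plot_id, levels = plots$plot_id))
    for (i in seq_len(nrow(plots))) {
      tr <- split_trees[[i]]
      if (is.null(tr) || nrow(tr) == 0) next
      alive <- tr[tr$status == "alive", , drop = FALSE]
      out$dead_tree_density[i] <- sum(tr$status == "dead") * per_ha
      if (nrow(alive) == 0) next
      out$tree_dbh_mean[i] <- mean(alive$dbh_mm)
      out$tree_height_mean[i] <- mean(alive$height_m)
      out$dbh_range[i] <- max(alive$dbh_mm) - min(alive$dbh_mm)
      out$height_range[i] <- max(alive$height_m) - min(alive$height_m)
      out$tree_density[i] <- nrow(alive) * per_ha
      large <- alive$dbh_mm > large_dbh_mm
      out$large_tree_density[i] <- sum(large) * per_ha
      out$softwood_large_density[i] <- sum(large & alive$wood == "soft") * per_ha
      out$tree_richness[i] <- length(unique(alive$species_code))
      ba <- ba_m2(alive$dbh_mm)
      out$basal_area[i] <- sum(ba) * per_ha
      out$wood_density_mean[i] <- sum(ba * alive$wood_density_g_cm3) / sum(ba)
      ba_sp <- tapply(ba, alive$species_code, sum)
      top <- names(ba_sp)[ba_sp == max(ba_sp)]
      out$dominant_species[i] <- sort(top)[1L]
    }
  }
  rownames(out) <- NULL
  out
}

#' Extract climate raster values to plots
#'
#' Nearest-cell extraction of each climate raster at plot locations. Plots
#' outside a raster extent get `NA` and are flagged for downstream exclusion.
#'
#' @param plot_vars plot-variables data frame with `x_m`, `y_m`.
#' @param rasters named list of [grid_raster()] objects.
#' @return `plot_vars` with one added column per raster plus a logical
#'   `climate_complete` flag.
#' @export
extract_climate_to_plots <- function(plot_vars, rasters) {
  stopifnot(is.list(rasters), length(names(rasters)) == length(rasters))
  for (nm in names(rasters)) {
    r <- rasters[[nm]]
    stopifnot(inherits(r, "grid_raster"))
    vals <- raster_extract(r, plot_vars$x_m, plot_vars$y_m)
    if (nrow(plot_vars) > 0 && all(is.na(vals)))
      stop_fsd(paste("interface error: no plot falls inside raster '%s';",
                     "coordinate scales are inconsistent"), nm)
    plot_vars[[nm]] <- vals
  }
  cl <- as.matrix(plot_vars[, names(rasters), drop = FALSE])
  plot_vars$climate_complete <- if (length(rasters)) rowSums(is.na(cl)) == 0 else TRUE
  plot_vars
}

#' Greedy correlation screening of quantitative variables
#'
#' Walks the supplied ranking (best first) and retains a variable only if its
#' absolute Pearson correlation with every already-retained variable is below
#' the threshold. Zero-variance variables are dropped with a warning.
#' Categorical variables are not screened and pass through.
#'
#' @param data data frame holding the variables.
#' @param ranking character vector of quantitative variable names, best first.
#' @param threshold absolute-correlation cutoff (default 0.70); a candidate
#'   with `|r| >= threshold` against any retained variable is dropped.
#' @param categorical character vector of categorical variable names passed
#'   through untouched.
#' @return list with `retained` (quantitative, in ranking order),
#'   `dropped` (named character: variable -> reason), `categorical`.
#' @export
screen_correlated <- function(data, ranking, threshold = 0.70,
                              categorical = character(0)) {
  stopifnot(all(ranking %in% names(data)))
  retained <- character(0)
  dropped <- character(0)
  for (v in ranking) {
    x <- data[[v]]
    if (!is.numeric(x)) stop_fsd("ranked variable '%s' is not quantitative", v)
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      warning(sprintf("variable '%s' has zero variance; dropped", v))
      dropped[v] <- "zero variance"
      next
    }
    conflict <- NULL
    for (u in retained) {
      r <- suppressWarnings(stats::cor(x, data[[u]],
                                       use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) >= threshold) { conflict <- u; break }
    }
    if (is.null(conflict)) retained <- c(retained, v)
    else dropped[v] <- sprintf("|r| >= %.2f with %s", threshold, conflict)
  }
  list(retained = retained, dropped = dropped, categorical = categorical)
}

#' Rank variables by single-variable model training gain
#'
#' Fits a one-variable Maxent model per candidate variable and sorts the
#' variables by decreasing training gain. Variables whose fit fails rank
#' last (gain `NA`).
#'
#' @param presences,backgrounds EnvSample-style data frames holding the
#'   variables at presence and background points.
#' @param variables character vector of variable names to rank.
#' @param classes feature classes for the single-variable models (default
#'   `"LQ"`).
#' @param rm regularization multiplier (default 1).
#' @param n_hinge_knots hinge knots per direction if `H` is in `classes`.
#' @return data.frame with `variable`, `gain`, sorted by decreasing gain.
#' @export
rank_by_single_variable_gain <- function(presences, backgrounds, variables,
                                         classes = "LQ", rm = 1,
                                         n_hinge_knots = 10) {
  gains <- vapply(variables, function(v) {
    tryCatch({
      fe <- expand_features(presences, backgrounds, vars = v, classes = classes,
                            n_hinge_knots = n_hinge_knots)
      m <- maxent_fit(fe, rm = rm)
      m$gain
    }, error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(variable = variables, gain = gains, stringsAsFactors = FALSE)
  out <- out[order(-out$gain, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
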