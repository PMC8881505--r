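## Synthetic forest landscapes, inventory plots, climate surfaces and virtual
## species. The generator emulates the statistical structure the downstream
## analysis assumes: 25-m-diameter inventory plots on a regular 1-km grid
## restricted to forested land, trees recorded above 75 mm DBH, smooth
## spatially autocorrelated climate surfaces, and species whose occurrence
## probability is a stated function of forest and/or climate variables.

#' Species pool used by the synthetic landscape
#'
#' Eight Mediterranean tree taxa with wood type and typical dry wood density.
#' @return data.frame with columns `species_code`, `wood`, `wood_density_g_cm3`.
#' @export
species_pool <- function() {
  data.frame(
    species_code = c("Phal", "Ppia", "Ppin", "Pnig", "Psyl", "Qile", "Qsub", "Qpyr"),
    wood = c("soft", "soft", "soft", "soft", "soft", "hard", "hard", "hard"),
    wood_density_g_cm3 = c(0.51, 0.53, 0.52, 0.56, 0.47, 0.90, 0.85, 0.80),
    stringsAsFactors = FALSE
  )
}

#' Stand model parameters for tree generation
#'
#' Diameters are drawn from a two-component truncated-lognormal mixture:
#' a "young" component of dense planted stands and a "mature" component in
#' which a configurable fraction of trees exceeds the 425 mm large-tree
#' threshold. All trees satisfy the inventory inclusion rule DBH > 75 mm.
#'
#' @param p_mature probability that a plot is a mature stand.
#' @param large_tree_prob within mature stands, probability a tree exceeds
#'   425 mm DBH.
#' @param dead_prob probability that a tree is standing dead.
#' @param stems_young,stems_mature Poisson mean stem count per plot.
#' @return list of stand parameters.
#' @export
stand_model <- function(p_mature = 0.3, large_tree_prob = 0.25, dead_prob = 0.06,
                        stems_young = 22, stems_mature = 12) {
  stopifnot(p_mature >= 0, p_mature <= 1, large_tree_prob >= 0, large_tree_prob <= 1)
  list(p_mature = p_mature, large_tree_prob = large_tree_prob,
       dead_prob = dead_prob, stems_young = stems_young, stems_mature = stems_mature)
}

## lognormal truncated to (lo, hi], by inverse CDF
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi = Inf) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

#' Draw tree diameters for one stand
#'
#' @param n number of trees.
#' @param type `"young"` or `"mature"`.
#' @param large_tree_prob probability of the >425 mm component (mature only).
#' @return numeric DBH vector in mm, all > 75.
#' @export
draw_dbh <- function(n, type = c("young", "mature"), large_tree_prob = 0.25) {
  type <- match.arg(type)
  if (n == 0L) return(numeric(0))
  if (type == "young") {
    rlnorm_trunc(n, log(150), 0.30, 75, 425)
  } else {
    big <- stats::runif(n) < large_tree_prob
    d <- numeric(n)
    d[big] <- rlnorm_trunc(sum(big), log(560), 0.22, 425, Inf)
    d[!big] <- rlnorm_trunc(sum(!big), log(230), 0.42, 75, 425)
    d
  }
}

#' Default climate field parameters
#'
#' Mean, marginal amplitude (standard deviation) and spatial length scale (m)
#' for the four climatic/topographic surfaces used in the models: elevation
#' (m), annual precipitation (mm), maximum temperature of the warmest month
#' (degC) and temperature seasonality (SD x 100).
#' @return named list of per-variable parameter lists.
#' @export
default_climate_params <- function() {
  list(
    elevation        = list(mean = 800,  amplitude = 350, length_scale_m = 9000),
    annual_precip    = list(mean = 620,  amplitude = 140, length_scale_m = 12000),
    tmax_warmest     = list(mean = 31,   amplitude = 2.5, length_scale_m = 14000),
    temp_seasonality = list(mean = 6000, amplitude = 450, length_scale_m = 16000)
  )
}

#' Landscape generator configuration
#'
#' @param extent_km width/height of the square study region (km).
#' @param plot_spacing_km spacing of the inventory plot grid (km).
#' @param plot_diameter_m diameter of circular inventory plots (m).
#' @param forest_fraction proportion of land that is forested, in `[0, 1]`.
#' @param climate_field_params per-variable `mean`/`amplitude`/`length_scale_m`,
#'   as in [default_climate_params()].
#' @param stand a [stand_model()].
#' @param landcover_res_m fine land-cover raster resolution (m).
#' @param climate_res_m climate raster resolution (m).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return A validated configuration list of class `landscape_config`.
#' @export
landscape_config <- function(extent_km = 20, plot_spacing_km = 1, plot_diameter_m = 25,
                             forest_fraction = 0.7,
                             climate_field_params = default_climate_params(),
                             stand = stand_model(),
                             landcover_res_m = 100, climate_res_m = 1000, seed = 1L) {
  if (!is.numeric(extent_km) || extent_km <= 0)
    stop_fsd("configuration error: extent_km must be positive (got %s)", extent_km)
  if (!is.numeric(plot_spacing_km) || plot_spacing_km <= 0)
    stop_fsd("configuration error: plot_spacing_km must be positive (got %s)", plot_spacing_km)
  if (forest_fraction < 0 || forest_fraction > 1)
    stop_fsd("configuration error: forest_fraction must lie in [0, 1]")
  structure(list(
    extent_km = extent_km, plot_spacing_km = plot_spacing_km,
    plot_diameter_m = plot_diameter_m, forest_fraction = forest_fraction,
    climate_field_params = climate_field_params, stand = stand,
    landcover_res_m = landcover_res_m, climate_res_m = climate_res_m,
    seed = as.integer(seed)
  ), class = "landscape_config")
}

#' Smooth random surface as a sum of low-frequency cosine bases
#'
#' Cheap, seedable stand-in for a Gaussian-process draw: `n_waves` plane
#' cosines with random directions, wavelengths near the length scale and
#' random phases, scaled so that the marginal standard deviation is
#' approximately `amplitude`.
#'
#' @param nr,nc raster dimensions.
#' @param cellsize cell size (m).
#' @param mean,amplitude marginal mean and standard deviation of the field.
#' @param length_scale_m dominant spatial wavelength (m).
#' @param n_waves number of cosine components.
#' @param xll,yll grid origin.
#' @return A [grid_raster()].
#' @export
cosine_field <- function(nr, nc, cellsize, mean = 0, amplitude = 1,
                         length_scale_m = 5000, n_waves = 8L, xll = 0, yll = 0) {
  theta <- stats::runif(n_waves, 0, 2 * pi)
  wl <- length_scale_m * stats::runif(n_waves, 0.6, 1.6)
  phase <- stats::runif(n_waves, 0, 2 * pi)
  xc <- xll + (seq_len(nc) - 0.5) * cellsize
  yc <- yll + (nr:1 - 0.5) * cellsize     # row 1 = north
  v <- matrix(0, nr, nc)
  for (k in seq_len(n_waves)) {
    px <- outer(yc * sin(theta[k]), xc * cos(theta[k]), "+")
    v <- v + cos(2 * pi * px / wl[k] + phase[k])
  }
  grid_raster(mean + amplitude * sqrt(2 / n_waves) * v, xll, yll, cellsize)
}

#' Generate a synthetic forest landscape
#'
#' Produces (i) a binary forest land-cover raster whose forested proportion
#' matches `forest_fraction` by thresholding a smooth field at its empirical
#' quantile, (ii) inventory plots on the regular plot grid restricted to
#' forested cells, (iii) a per-tree table obeying the DBH > 75 mm inclusion
#' rule, drawn from the configured stand model, and (iv) smooth climate
#' rasters.
#'
#' @param config a [landscape_config()].
#' @return list with elements `plots` (plot_id, x_m, y_m, stand_type,
#'   tree_cover, understory_cover, plantation_pct, development_stage),
#'   `trees` (plot_id, species_code, dbh_mm, height_m, status, wood,
#'   wood_density_g_cm3), `climate` (named list of [grid_raster()]),
#'   `landcover` ([grid_raster()]), and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  ext_m <- config$extent_km * 1000

  ## forest mask: threshold a smooth field at the (1 - fraction) quantile
  nlc <- round(ext_m / config$landcover_res_m)
  base <- cosine_field(nlc, nlc, config$landcover_res_m,
                       length_scale_m = ext_m / 5, n_waves = 10L)
  if (config$forest_fraction >= 1) {
    mask <- matrix(1, nlc, nlc)
  } else if (config$forest_fraction <= 0) {
    mask <- matrix(0, nlc, nlc)
  } else {
    thr <- stats::quantile(base$values, 1 - config$forest_fraction, type = 7)
    mask <- (base$values > thr) * 1
  }
  landcover <- grid_raster(mask, 0, 0, config$landcover_res_m)

  ## climate rasters
  ncl <- round(ext_m / config$climate_res_m)
  climate <- lapply(config$climate_field_params, function(p) {
    cosine_field(ncl, ncl, config$climate_res_m, mean = p$mean,
                 amplitude = p$amplitude, length_scale_m = p$length_scale_m)
  })

  ## plot grid: nodes at cell centres of the plot grid, kept where forested
  sp_m <- config$plot_spacing_km * 1000
  n_nodes <- floor(config$extent_km / config$plot_spacing_km)
  if (n_nodes < 1L) stop_fsd("configuration error: extent smaller than plot spacing")
  coord <- (seq_len(n_nodes) - 0.5) * sp_m
  grid <- expand.grid(x_m = coord, y_m = coord)
  forested <- raster_extract(landcover, grid$x_m, grid$y_m) == 1
  grid <- grid[forested, , drop = FALSE]

  n_plots <- nrow(grid)
  stn <- config$stand
  ## mature stands form spatially contiguous pockets: threshold a smooth
  ## field (plus a little plot-level noise) at the configured mature fraction
  if (n_plots > 0) {
    sf <- cosine_field(n_nodes, n_nodes, sp_m, length_scale_m = ext_m / 6,
                       n_waves = 8L)
    sval <- raster_extract(sf, grid$x_m, grid$y_m) + stats::rnorm(n_plots, 0, 0.35)
    thr <- stats::quantile(sval, 1 - stn$p_mature, type = 7)
    stand_type <- ifelse(sval > thr, "mature", "young")
  } else stand_type <- character(0)
  dev_stage <- ifelse(stand_type == "mature",
                      sample(3:5, n_plots, replace = TRUE),
                      sample(1:3, n_plots, replace = TRUE))
  plots <- data.frame(
    plot_id = sprintf("P%05d", seq_len(n_plots)),
    x_m = grid$x_m, y_m = grid$y_m,
    stand_type = stand_type,
    tree_cover = pmin(95, pmax(5, stats::rnorm(n_plots,
      ifelse(stand_type == "young", 70, 55), 12))),
    understory_cover = pmin(95, pmax(0, stats::rnorm(n_plots,
      ifelse(stand_type == "young", 45, 25), 15))),
    plantation_pct = ifelse(stand_type == "young",
      pmin(100, pmax(0, stats::rnorm(n_plots, 60, 25))),
      pmin(100, pmax(0, stats::rnorm(n_plots, 10, 10)))),
    development_stage = dev_stage,
    stringsAsFactors = FALSE
  )

  pool <- species_pool()
  trees <- data.frame(plot_id = character(0), species_code = character(0),
                      dbh_mm = numeric(0), height_m = numeric(0),
                      status = character(0), wood = character(0),
                      wood_density_g_cm3 = numeric(0))
  if (n_plots > 0) {
    ## spatial preference for hardwoods at higher plots adds realistic
    ## composition-climate correlation
    elev <- if (!is.null(climate$elevation))
      raster_extract(climate$elevation, plots$x_m, plots$y_m) else rep(0, n_plots)
    elev[is.na(elev)] <- mean(elev, na.rm = TRUE)
    ez <- if (n_plots > 1 && isTRUE(stats::sd(elev) > 0))
      (elev - mean(elev)) / stats::sd(elev) else elev * 0
    p_hard <- stats::plogis(ez * 0.8)
    mature_plot <- stand_type == "mature"
    n_tr <- stats::rpois(n_plots, ifelse(mature_plot, stn$stems_mature,
                                         stn$stems_young))
    ## each plot is dominated by one species plus admixture
    hard_pool <- c("Qile", "Qsub", "Qpyr")
    soft_pool <- c("Phal", "Ppia", "Ppin", "Pnig", "Psyl")
    dom <- ifelse(stats::runif(n_plots) < p_hard,
                  sample(hard_pool, n_plots, replace = TRUE),
                  sample(soft_pool, n_plots, replace = TRUE))
    pid <- rep(seq_len(n_plots), n_tr)
    total <- length(pid)
    if (total > 0) {
      mature_tree <- mature_plot[pid]
      dbh <- numeric(total)
      dbh[!mature_tree] <- draw_dbh(sum(!mature_tree), "young")
      dbh[mature_tree] <- draw_dbh(sum(mature_tree), "mature",
                                   stn$large_tree_prob)
      sp <- ifelse(stats::runif(total) < 0.75, dom[pid],
                   sample(pool$species_code, total, replace = TRUE))
      height <- pmax(2, 1.3 + 0.9 * (dbh / 10)^0.8 + stats::rnorm(total, 0, 1.2))
      status <- ifelse(stats::runif(total) < stn$dead_prob, "dead", "alive")
      idx <- match(sp, pool$species_code)
      trees <- data.frame(
        plot_id = plots$plot_id[pid], species_code = sp, dbh_mm = dbh,
        height_m = height, status = status, wood = pool$wood[idx],
        wood_density_g_cm3 = pool$wood_density_g_cm3[idx],
        stringsAsFactors = FALSE
      )
    }
  }
  rownames(trees) <- NULL
  list(plots = plots, trees = trees, climate = climate,
       landcover = landcover, config = config)
}

#' Define a virtual species
#'
#' A virtual species has functional traits (roosting ecology, wing loading,
#' aspect ratio) and a suitability model: a list of response terms, each a
#' `list(variable, form, coef)` with `form` one of `"linear"` (standardized
#' value), `"logistic"` (saturating response to the standardized value) or
#' `"threshold"` (indicator of the variable exceeding its upper quartile
#' across plots). Occurrence probability is the logistic link of the summed
#' terms.
#'
#' @param name species label.
#' @param roosting `"tree"` or `"non-tree"`.
#' @param wing_loading wing loading (N/m^2).
#' @param aspect_ratio wing aspect ratio (dimensionless).
#' @param response_terms list of response terms (see Details).
#' @param n_occurrences number of occurrence records to simulate (>= 1).
#' @param forager_class `"within-forest"` or `"open-space"`.
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(name, roosting = c("tree", "non-tree"),
                            wing_loading = 8, aspect_ratio = 6,
                            response_terms = list(), n_occurrences = 50,
                            forager_class = c("within-forest", "open-space")) {
  roosting <- match.arg(roosting)
  forager_class <- match.arg(forager_class)
  if (n_occurrences < 1) stop_fsd("n_occurrences must be >= 1")
  for (tm in response_terms) {
    stopifnot(is.list(tm), !is.null(tm$variable), !is.null(tm$form), !is.null(tm$coef))
    if (!tm$form %in% c("linear", "logistic", "threshold"))
      stop_fsd("unknown response form '%s'", tm$form)
  }
  structure(list(name = name, roosting = roosting, wing_loading = wing_loading,
                 aspect_ratio = aspect_ratio, response_terms = response_terms,
                 n_occurrences = as.integer(n_occurrences),
                 forager_class = forager_class),
            class = "virtual_species")
}

#' Per-plot suitability of a virtual species
#'
#' @param species a [virtual_species()].
#' @param plot_vars plot-variables data frame (see [compute_plot_variables()]).
#' @return numeric vector of suitabilities in `(0, 1)`, one per plot.
#' @export
species_suitability <- function(species, plot_vars) {
  stopifnot(inherits(species, "virtual_species"))
  lp <- rep(0, nrow(plot_vars))
  for (tm in species$response_terms) {
    if (!tm$variable %in% names(plot_vars))
      stop_fsd("response term references unknown variable '%s'", tm$variable)
    x <- plot_vars[[tm$variable]]
    if (!is.numeric(x)) stop_fsd("response variable '%s' is not quantitative", tm$variable)
    s <- stats::sd(x)
    z <- if (s > 0) (x - mean(x)) / s else x * 0
    ## all forms are centred so that a positive coefficient depresses
    ## suitability below the feature's centre and raises it above
    val <- switch(tm$form,
      linear = z,
      logistic = 2 * (stats::plogis(2 * z) - 0.5),
      threshold = 2 * as.numeric(x > stats::quantile(x, 0.75, type = 7)) - 1)
    lp <- lp + tm$coef * val
  }
  stats::plogis(lp)
}

#' Sample occurrence records for a virtual species
#'
#' Plots are sampled with replacement proportionally to suitability; each
#' record is jittered uniformly within `jitter_m` of its plot, emulating
#' capture sites offset from the habitat the record represents.
#'
#' @param species a [virtual_species()].
#' @param plot_vars plot-variables data frame with `x_m`, `y_m`.
#' @param seed integer seed.
#' @param jitter_m jitter radius (m), default 300.
#' @return data.frame: `species`, `x_m`, `y_m`, `date_iso`, `method`.
#' @export
sample_occurrences <- function(species, plot_vars, seed = 1L, jitter_m = 300) {
  stopifnot(inherits(species, "virtual_species"))
  if (nrow(plot_vars) == 0)
    stop_fsd("degenerate species '%s': no plots to sample from", species$name)
  suit <- species_suitability(species, plot_vars)
  if (sum(suit) <= 0)
    stop_fsd("degenerate species '%s': suitability is zero everywhere", species$name)
  set.seed(seed)
  n <- species$n_occurrences
  idx <- sample.int(nrow(plot_vars), n, replace = TRUE, prob = suit)
  r <- jitter_m * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  data.frame(
    species = species$name,
    x_m = plot_vars$x_m[idx] + r * cos(a),
    y_m = plot_vars$y_m[idx] + r * sin(a),
    date_iso = sprintf("%04d-%02d-%02d", sample(1997:2007, n, TRUE),
                       sample(3:11, n, TRUE), sample(1:28, n, TRUE)),
    method = sample(c("mist-net", "harp-trap", "acoustic"), n, TRUE,
                    prob = c(0.6, 0.35, 0.05)),
    stringsAsFactors = FALSE
  )
}
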