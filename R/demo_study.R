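## Bundled synthetic study: a nine-species virtual forest-bat community on a
## synthetic Mediterranean landscape. Four tree-roosting species respond to
## roost-availability variables (large-tree and softwood large-tree
## densities), five cave/building-roosting species respond to climate. Trait
## values are synthetic stand-ins chosen to mirror the structure of a real
## Mediterranean assemblage: tree-roosters have higher wing loading, and the
## two open-space foragers are excluded from wing-morphology tests.

#' Landscape configuration of the bundled synthetic study
#'
#' A 60 x 60 km region with 70% forest cover, inventory plots on a 1-km
#' grid, and the default climate surfaces — large enough for background
#' thinning at 4-5 km to yield roughly two hundred background samples.
#'
#' @param seed integer seed.
#' @return A [landscape_config()].
#' @export
demo_landscape_config <- function(seed = 1L) {
  landscape_config(extent_km = 60, plot_spacing_km = 1, forest_fraction = 0.7,
                   seed = seed)
}

#' Virtual species set of the bundled synthetic study
#'
#' Nine virtual species: four tree-roosting species whose suitability is
#' driven by roost-availability variables, and five non-tree-roosting
#' species driven by climate. `effect` scales the response coefficients
#' (1 = the default study conditions).
#'
#' @param effect multiplier on all response coefficients.
#' @return Named list of [virtual_species()].
#' @export
demo_species_set <- function(effect = 1) {
  roost <- function(c1, c2) list(
    list(variable = "large_tree_density", form = "linear", coef = c1 * effect),
    list(variable = "softwood_large_density", form = "linear", coef = c2 * effect))
  clim <- function(v1, c1, v2, c2) list(
    list(variable = v1, form = "linear", coef = c1 * effect),
    list(variable = v2, form = "linear", coef = c2 * effect))
  list(
    Bbar = virtual_species("Bbar", "tree", 7.9, 5.9, roost(4.0, 2.5), 40),
    Mbec = virtual_species("Mbec", "tree", 8.7, 6.0, roost(5.0, 2.0), 49),
    Nlas = virtual_species("Nlas", "tree", 15.0, 7.4, roost(4.0, 2.0), 48,
                           forager_class = "open-space"),
    Nleis = virtual_species("Nleis", "tree", 11.6, 6.9, roost(4.5, 1.5), 48,
                            forager_class = "open-space"),
    Mema = virtual_species("Mema", "non-tree", 7.6, 6.1,
                           clim("elevation", 2.5, "annual_precip", 1.5), 80),
    Mes = virtual_species("Mes", "non-tree", 7.0, 6.3,
                          clim("annual_precip", 3.0, "tmax_warmest", -1.2), 90),
    Paus = virtual_species("Paus", "non-tree", 6.8, 5.8,
                           clim("tmax_warmest", -2.5, "temp_seasonality", 1.2), 90),
    Reur = virtual_species("Reur", "non-tree", 7.0, 5.5,
                           clim("elevation", -2.0, "annual_precip", 2.0), 100),
    Rhip = virtual_species("Rhip", "non-tree", 5.0, 5.7,
                           clim("temp_seasonality", -2.0, "elevation", 1.5), 110)
  )
}

#' Spatial parameters of the bundled synthetic study
#'
#' Home-range classes mirroring the structure of a real assemblage: the two
#' open-space foragers are mobile, one tree-rooster is intermediate, the
#' rest are less mobile.
#'
#' @return Named list of [spatial_params()], one per demo species.
#' @export
demo_spatial_params <- function() {
  list(
    Bbar = spatial_params("intermediate"),
    Mbec = spatial_params("less-mobile"),
    Nlas = spatial_params("mobile"),
    Nleis = spatial_params("mobile"),
    Mema = spatial_params("less-mobile"),
    Mes = spatial_params("less-mobile"),
    Paus = spatial_params("less-mobile"),
    Reur = spatial_params("less-mobile"),
    Rhip = spatial_params("less-mobile")
  )
}

#' Default model settings of the bundled synthetic study
#'
#' A fixed linear + quadratic feature set at regularization multiplier 1,
#' with the initial background draw and cap sized for the 60-km demo region.
#'
#' @param ... overrides passed to [model_settings()].
#' @return A [model_settings()] list.
#' @export
demo_model_settings <- function(...) {
  args <- list(...)
  base <- list(classes = "LQ", rm = 1, n_bg_init = 2000, n_bg_max = 200,
               nfolds = 6)
  do.call(model_settings, utils::modifyList(base, args))
}
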