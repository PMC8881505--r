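## Spatial thinning, home-range-scaled interpolation of plot variables to
## points, background generation and the forest-proportion layer. All
## distances are planar Euclidean on projected metre coordinates.

#' Home-range-dependent spatial parameters for a species
#'
#' Defaults follow three mobility classes: less-mobile species use the
#' closest 2-5 plots within 3 km with 500 m presence thinning; intermediate
#' species 4-8 plots within 5 km with 1000 m thinning; mobile species 8-16
#' plots within 7 km with 2000 m thinning. Background points are thinned at
#' 4-5 km and plots within the same buffer of any presence are excluded from
#' the background interpolation pool.
#'
#' @param mobility one of `"less-mobile"`, `"intermediate"`, `"mobile"`.
#' @param k_min,k_max minimum/maximum number of plots interpolated to a point.
#' @param d_max_km maximum plot distance (km).
#' @param thin_presence_m presence un-clustering distance (m).
#' @param thin_background_km background thinning distance (km).
#' @param exclusion_km presence-background plot exclusion buffer (km).
#' @return list of class `species_spatial_params`.
#' @export
spatial_params <- function(mobility = c("less-mobile", "intermediate", "mobile"),
                           k_min = NULL, k_max = NULL, d_max_km = NULL,
                           thin_presence_m = NULL, thin_background_km = NULL,
                           exclusion_km = NULL) {
  mobility <- match.arg(mobility)
  def <- switch(mobility,
    "less-mobile"  = list(k_min = 2, k_max = 5,  d_max_km = 3, thin_presence_m = 500,
                          thin_background_km = 4, exclusion_km = 4),
    "intermediate" = list(k_min = 4, k_max = 8,  d_max_km = 5, thin_presence_m = 1000,
                          thin_background_km = 4, exclusion_km = 4),
    "mobile"       = list(k_min = 8, k_max = 16, d_max_km = 7, thin_presence_m = 2000,
                          thin_background_km = 5, exclusion_km = 5))
  p <- list(mobility = mobility,
            k_min = k_min %||% def$k_min, k_max = k_max %||% def$k_max,
            d_max_km = d_max_km %||% def$d_max_km,
            thin_presence_m = thin_presence_m %||% def$thin_presence_m,
            thin_background_km = thin_background_km %||% def$thin_background_km,
            exclusion_km = exclusion_km %||% def$exclusion_km)
  if (p$k_min < 1 || p$k_min > p$k_max)
    stop_fsd("invalid spatial params: need 1 <= k_min <= k_max")
  if (p$d_max_km <= 0) stop_fsd("invalid spatial params: d_max_km must be > 0")
  class(p) <- "species_spatial_params"
  p
}

#' Spatially thin (un-cluster) a point set
#'
#' Iterative greedy elimination: while any pair is closer than `min_dist`,
#' remove the point with the most neighbours within `min_dist`; ties are
#' broken at random under the given seed. The result is a subset of the
#' input in which all pairwise distances are at least `min_dist`.
#'
#' @param points data frame or matrix with `x_m`, `y_m` (or two columns).
#' @param min_dist minimum allowed pairwise distance (m), > 0.
#' @param seed integer seed for tie-breaking.
#' @return The retained subset (same class as input), with the retained row
#'   indices in attribute `"kept"`.
#' @export
thin_points <- function(points, min_dist, seed = 1L) {
  stopifnot(min_dist > 0)
  xy <- if (is.data.frame(points)) cbind(points$x_m, points$y_m) else as.matrix(points)
  n <- nrow(xy)
  if (n <= 1L) {
    out <- points
    attr(out, "kept") <- seq_len(n)
    return(out)
  }
  set.seed(seed)
  ## neighbour lists via cell bucketing: candidates only come from the 3x3
  ## block of min_dist-sized cells around a point, so memory stays O(pairs)
  cx <- as.integer(floor(xy[, 1] / min_dist)); cx <- cx - min(cx)
  cy <- as.integer(floor(xy[, 2] / min_dist)); cy <- cy - min(cy)
  nx <- max(cx) + 1L; ny <- max(cy) + 1L
  cell <- cx + nx * cy + 1L
  buckets <- split(seq_len(n), factor(cell, levels = seq_len(nx * ny)))
  off <- expand.grid(dx = -1:1, dy = -1:1)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    ncx <- cx[i] + off$dx; ncy <- cy[i] + off$dy
    ok <- ncx >= 0L & ncx < nx & ncy >= 0L & ncy < ny
    cand <- unlist(buckets[ncx[ok] + nx * ncy[ok] + 1L], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      dd2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
      nbrs[[i]] <- cand[dd2 < min_dist^2]
    } else nbrs[[i]] <- integer(0)
  }
  alive <- rep(TRUE, n)
  counts <- lengths(nbrs)
  while (any(counts[alive] > 0)) {
    mx <- max(counts[alive])
    cand <- which(alive & counts == mx)
    drop <- if (length(cand) == 1L) cand else sample(cand, 1L)
    alive[drop] <- FALSE
    nb <- nbrs[[drop]][alive[nbrs[[drop]]]]
    counts[nb] <- counts[nb] - 1L
    counts[drop] <- 0L
  }
  kept <- which(alive)
  out <- if (is.data.frame(points)) points[kept, , drop = FALSE] else
    points[kept, , drop = FALSE]
  attr(out, "kept") <- kept
  out
}

#' Interpolate plot variables to points at home-range scale
#'
#' For each point, selects the nearest up to `k_max` plots within `d_max_km`;
#' a point with fewer than `k_min` qualifying plots is dropped (with the
#' reason logged in the result). Quantitative variables are averaged,
#' categorical variables take the mode with ties broken by the nearest
#' plot's value.
#'
#' @param points data frame with `x_m`, `y_m`.
#' @param plot_vars plot-variables data frame (with `x_m`, `y_m`).
#' @param params a [spatial_params()].
#' @param quantitative,categorical variable names to interpolate.
#' @param label label for the resulting EnvSamples (`"presence"` or
#'   `"background"`).
#' @return list with `samples` (EnvSample data frame: `label`, coordinates,
#'   `n_plots_used`, `mean_plot_distance_m`, interpolated variables; the
#'   per-row plot indices used are in attribute `"plots_used"`) and
#'   `dropped` (data frame of dropped points with reasons).
#' @export
interpolate_to_points <- function(points, plot_vars, params,
                                  quantitative, categorical = character(0),
                                  label = "presence") {
  stopifnot(inherits(params, "species_spatial_params"))
  stopifnot(all(quantitative %in% names(plot_vars)),
            all(categorical %in% names(plot_vars)))
  n <- nrow(points)
  d_max <- params$d_max_km * 1000
  if (n == 0L || nrow(plot_vars) == 0L) {
    empty <- points[0, c("x_m", "y_m"), drop = FALSE]
    return(list(samples = cbind(data.frame(label = character(0)), empty),
                dropped = data.frame(x_m = points$x_m, y_m = points$y_m,
                                     reason = rep("no plots available", n))))
  }
  d <- xy_dist(cbind(points$x_m, points$y_m),
               cbind(plot_vars$x_m, plot_vars$y_m))
  used <- vector("list", n)
  drop_reason <- rep(NA_character_, n)
  qmat <- matrix(NA_real_, n, length(quantitative),
                 dimnames = list(NULL, quantitative))
  cmat <- matrix(NA_character_, n, length(categorical),
                 dimnames = list(NULL, categorical))
  n_used <- integer(n); mean_d <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    ok <- which(di <= d_max)
    if (length(ok) < params$k_min) {
      drop_reason[i] <- sprintf("only %d plot(s) within %.1f km (need >= %d)",
                                length(ok), params$d_max_km, params$k_min)
      next
    }
    sel <- ok[order(di[ok])][seq_len(min(params$k_max, length(ok)))]
    n_used[i] <- length(sel)
    mean_d[i] <- mean(di[sel])
    for (v in quantitative) qmat[i, v] <- mean(plot_vars[[v]][sel])
    for (v in categorical) {
      vals <- as.character(plot_vars[[v]][sel])
      ## tie preference: value of the nearest plot first, then nearest order
      cmat[i, v] <- mode_stat(vals, pref = vals)
    }
    used[[i]] <- sel
  }
  keep <- is.na(drop_reason)
  samples <- data.frame(label = rep(label, sum(keep)),
                        x_m = points$x_m[keep], y_m = points$y_m[keep],
                        n_plots_used = n_used[keep],
                        mean_plot_distance_m = mean_d[keep],
                        stringsAsFactors = FALSE)
  for (v in quantitative) samples[[v]] <- qmat[keep, v]
  for (v in categorical) samples[[v]] <- cmat[keep, v]
  rownames(samples) <- NULL
  attr(samples, "plots_used") <- used[keep]
  list(samples = samples,
       dropped = data.frame(x_m = points$x_m[!keep], y_m = points$y_m[!keep],
                            reason = drop_reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Generate background (pseudo-absence) samples
#'
#' Distributes `n_init` uniform random points across the region, thins them
#' at the species' background thinning distance, removes from the plot
#' interpolation pool every plot closer than the exclusion buffer to any
#' presence, and interpolates the surviving points with the species' spatial
#' parameters. Optionally subsamples to at most `n_max` background samples.
#'
#' @param region extent `c(xmin, xmax, ymin, ymax)` (m).
#' @param presences data frame of presence points (`x_m`, `y_m`); may be empty.
#' @param plot_vars plot-variables data frame.
#' @param params a [spatial_params()].
#' @param quantitative,categorical variable names to interpolate.
#' @param n_init initial number of random points (default 10000).
#' @param n_max optional cap on the number of background samples returned.
#' @param seed integer seed.
#' @return list as in [interpolate_to_points()] plus `n_excluded_plots`.
#' @export
generate_background <- function(region, presences, plot_vars, params,
                                quantitative, categorical = character(0),
                                n_init = 10000, n_max = NULL, seed = 1L) {
  stopifnot(length(region) == 4, region[2] > region[1], region[4] > region[3])
  set.seed(seed)
  pts <- data.frame(x_m = stats::runif(n_init, region[1], region[2]),
                    y_m = stats::runif(n_init, region[3], region[4]))
  pts <- thin_points(pts, params$thin_background_km * 1000,
                     seed = derive_seed(seed, "background-thin"))
  ## exclusion buffer: plots near presences leave the interpolation pool
  pool <- plot_vars
  n_excluded <- 0L
  if (!is.null(presences) && nrow(presences) > 0 && nrow(pool) > 0) {
    dmin <- apply(xy_dist(cbind(pool$x_m, pool$y_m),
                          cbind(presences$x_m, presences$y_m)), 1, min)
    keep <- dmin >= params$exclusion_km * 1000
    n_excluded <- sum(!keep)
    pool <- pool[keep, , drop = FALSE]
  }
  res <- interpolate_to_points(pts, pool, params, quantitative, categorical,
                               label = "background")
  if (nrow(res$samples) == 0)
    stop_fsd("pipeline error: zero background points survived thinning/interpolation")
  if (!is.null(n_max) && nrow(res$samples) > n_max) {
    set.seed(derive_seed(seed, "background-subsample"))
    idx <- sort(sample.int(nrow(res$samples), n_max))
    pu <- attr(res$samples, "plots_used")[idx]
    res$samples <- res$samples[idx, , drop = FALSE]
    rownames(res$samples) <- NULL
    attr(res$samples, "plots_used") <- pu
  }
  res$n_excluded_plots <- n_excluded
  res
}

#' Forest-proportion layer from a binary land-cover raster
#'
#' Reclassified land cover (forest = 1, other = 0) is aggregated by block
#' mean so each coarse cell holds the proportion of forested fine cells
#' (factor 25 turns a 100 m mask into a 2.5 km proportion layer).
#'
#' @param landcover binary [grid_raster()].
#' @param fact aggregation factor (default 25).
#' @return A [grid_raster()] of forest proportions in `[0, 1]`.
#' @export
forest_proportion_layer <- function(landcover, fact = 25) {
  stopifnot(inherits(landcover, "grid_raster"))
  v <- landcover$values
  if (!all(v[!is.na(v)] %in% c(0, 1)))
    stop_fsd("data error: land-cover raster is not binary (0/1)")
  raster_aggregate_mean(landcover, fact)
}
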