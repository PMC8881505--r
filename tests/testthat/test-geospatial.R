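test_that("thinning follows the greedy max-neighbour rule", {
  one <- data.frame(x_m = 3, y_m = 4)
  expect_equal(nrow(thin_points(one, 500)), 1)
  ## collinear points at 0, 400, 800 m: the middle point has two neighbours
  ## and is removed first, leaving {0, 800}
  tri <- data.frame(x_m = c(0, 400, 800), y_m = 0)
  th <- thin_points(tri, 500, seed = 1)
  expect_equal(th$x_m, c(0, 800))
  ## an already-thinned set comes back unchanged
  sp <- data.frame(x_m = c(0, 1000, 2000), y_m = 0)
  expect_equal(thin_points(sp, 500)$x_m, sp$x_m)
  ## empty input is allowed
  expect_equal(nrow(thin_points(sp[0, ], 500)), 0)
})

test_that("thinned sets satisfy the minimum-distance invariant on random inputs", {
  for (s in 1:20) {
    set.seed(s)
    pts <- data.frame(x_m = runif(80, 0, 4000), y_m = runif(80, 0, 4000))
    th <- thin_points(pts, 700, seed = s)
    if (nrow(th) > 1) {
      dmin <- min(dist(cbind(th$x_m, th$y_m)))
      expect_gte(dmin, 700)
    }
    ## output is a subset of the input
    expect_true(all(paste(th$x_m, th$y_m) %in% paste(pts$x_m, pts$y_m)))
    ## determinism
    th2 <- thin_points(pts, 700, seed = s)
    expect_identical(th, th2)
  }
})

test_that("interpolation selects nearest plots and respects k_min", {
  plots <- data.frame(plot_id = c("a", "b", "c"),
                      x_m = c(0, 1000, 9000), y_m = 0,
                      q = c(10, 20, 99), cat1 = c("A", "A", "B"),
                      stringsAsFactors = FALSE)
  p1 <- spatial_params("less-mobile", k_min = 1, k_max = 5, d_max_km = 2)
  ## one plot in range -> verbatim values
  r <- interpolate_to_points(data.frame(x_m = 8900, y_m = 0), plots, p1,
                             "q", "cat1")
  expect_equal(r$samples$q, 99)
  expect_equal(r$samples$cat1, "B")
  expect_equal(r$samples$n_plots_used, 1)
  ## two plots -> mean of quantitative, mode of categorical
  r2 <- interpolate_to_points(data.frame(x_m = 500, y_m = 0), plots, p1,
                              "q", "cat1")
  expect_equal(r2$samples$q, 15)
  expect_equal(r2$samples$cat1, "A")
  ## fewer than k_min plots in range -> dropped with a reason
  p2 <- spatial_params("less-mobile", k_min = 2, k_max = 5, d_max_km = 2)
  r3 <- interpolate_to_points(data.frame(x_m = 8900, y_m = 0), plots, p2,
                              "q", "cat1")
  expect_equal(nrow(r3$samples), 0)
  expect_match(r3$dropped$reason, "need >= 2")
})

test_that("interpolation equals a brute-force distance sort on random instances", {
  for (s in 1:15) {
    plots <- random_plot_table(seed = s, n = 40)
    set.seed(s + 1000)
    pts <- data.frame(x_m = runif(10, 0, 5000), y_m = runif(10, 0, 5000))
    par <- spatial_params("less-mobile", k_min = 2, k_max = 6, d_max_km = 1.5)
    res <- interpolate_to_points(pts, plots, par, c("a", "b"), "cat1")
    used <- attr(res$samples, "plots_used")
    kept <- 0
    for (i in seq_len(nrow(pts))) {
      d <- sqrt((plots$x_m - pts$x_m[i])^2 + (plots$y_m - pts$y_m[i])^2)
      ok <- which(d <= 1500)
      if (length(ok) < 2) next
      kept <- kept + 1
      sel <- ok[order(d[ok])][seq_len(min(6, length(ok)))]
      expect_equal(sort(used[[kept]]), sort(sel))
      expect_equal(res$samples$a[kept], mean(plots$a[sel]))
      expect_equal(res$samples$b[kept], mean(plots$b[sel]))
      expect_true(res$samples$n_plots_used[kept] >= 2 &&
                    res$samples$n_plots_used[kept] <= 6)
      expect_true(all(d[sel] <= 1500))
    }
    expect_equal(nrow(res$samples), kept)
  }
})

test_that("background generation excludes plots near presences and is deterministic", {
  st <- calib_landscape()
  par <- calib_params()
  pres <- data.frame(x_m = c(5000, 15000, 25000), y_m = c(5000, 15000, 25000))
  bg1 <- generate_background(st$region, pres, st$pv, par,
                             quantitative = c("tree_density", "basal_area"),
                             n_init = 800, seed = 9)
  bg2 <- generate_background(st$region, pres, st$pv, par,
                             quantitative = c("tree_density", "basal_area"),
                             n_init = 800, seed = 9)
  expect_identical(bg1$samples, bg2$samples)
  expect_gt(nrow(bg1$samples), 0)
  ## no background interpolation used an excluded plot
  ## reproduced independently from the restricted plot pool
  dmin <- apply(forestsdm:::xy_dist(cbind(st$pv$x_m, st$pv$y_m),
                                    cbind(pres$x_m, pres$y_m)), 1, min)
  pool_rows <- st$pv[dmin >= par$exclusion_km * 1000, ]
  redo <- interpolate_to_points(bg1$samples[, c("x_m", "y_m")], pool_rows, par,
                                c("tree_density", "basal_area"),
                                label = "background")
  expect_equal(redo$samples$tree_density, bg1$samples$tree_density)
  expect_equal(redo$samples$basal_area, bg1$samples$basal_area)
  expect_gt(bg1$n_excluded_plots, 0)
  ## no presences: thinning still applies, nothing excluded
  bg3 <- generate_background(st$region, pres[0, ], st$pv, par,
                             quantitative = "tree_density", n_init = 400,
                             seed = 9)
  expect_equal(bg3$n_excluded_plots, 0)
  ## an exclusion buffer larger than the region leaves nothing
  par_big <- spatial_params("less-mobile", exclusion_km = 100)
  expect_error(generate_background(st$region, pres, st$pv, par_big,
                                   quantitative = "tree_density",
                                   n_init = 200, seed = 1),
               "zero background")
})

test_that("forest-proportion layer validates binary input", {
  expect_error(forest_proportion_layer(grid_raster(matrix(c(0, 1, 2, 1), 2, 2))),
               "not binary")
  ok <- forest_proportion_layer(grid_raster(matrix(1, 50, 50), 0, 0, 100), 25)
  expect_true(all(ok$values == 1))
})
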