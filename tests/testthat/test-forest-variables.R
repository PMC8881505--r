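mk_plot <- function(id = "P1", x = 0, y = 0) {
  data.frame(plot_id = id, x_m = x, y_m = y, stringsAsFactors = FALSE)
}
mk_trees <- function(id, dbh, height = 10, status = "alive", wood = "hard",
                     sp = "Qile", wd = 0.9) {
  if (length(dbh) == 0)
    return(data.frame(plot_id = character(0), species_code = character(0),
                      dbh_mm = numeric(0), height_m = numeric(0),
                      status = character(0), wood = character(0),
                      wood_density_g_cm3 = numeric(0)))
  data.frame(plot_id = id, species_code = sp, dbh_mm = dbh,
             height_m = rep_len(height, length(dbh)),
             status = rep_len(status, length(dbh)),
             wood = rep_len(wood, length(dbh)),
             wood_density_g_cm3 = rep_len(wd, length(dbh)),
             stringsAsFactors = FALSE)
}

test_that("empty plots yield zero densities and a sentinel dominant species", {
  pv <- compute_plot_variables(mk_plot(), mk_trees("P1", numeric(0)))
  expect_equal(pv$tree_density, 0)
  expect_equal(pv$dead_tree_density, 0)
  expect_equal(pv$tree_richness, 0)
  expect_equal(pv$basal_area, 0)
  expect_equal(pv$dominant_species, "none")
})

test_that("per-hectare scaling matches hand arithmetic on the 25-m plot", {
  ## 3 live trees: 3 * 10000 / 490.874 = 61.12 stems/ha
  pv <- compute_plot_variables(mk_plot(), mk_trees("P1", c(100, 200, 300)))
  expect_equal(pv$tree_density, 3 * 10000 / (pi * 12.5^2), tolerance = 1e-10)
  expect_equal(round(pv$tree_density, 2), 61.12)
  ## one softwood tree of 450 mm: both large-tree densities = 20.37
  pv2 <- compute_plot_variables(mk_plot(), mk_trees("P1", 450, wood = "soft"))
  expect_equal(round(pv2$large_tree_density, 2), 20.37)
  expect_equal(pv2$softwood_large_density, pv2$large_tree_density)
})

test_that("plot variables equal a brute-force per-tree recomputation", {
  st <- study_landscape()
  ls <- st$landscape
  per_ha <- 10000 / (pi * 12.5^2)
  set.seed(8)
  for (pid in sample(ls$plots$plot_id, 25)) {
    tr <- ls$trees[ls$trees$plot_id == pid, ]
    alive <- tr[tr$status == "alive", ]
    row <- st$pv[st$pv$plot_id == pid, ]
    expect_equal(row$dead_tree_density, sum(tr$status == "dead") * per_ha)
    if (nrow(alive) == 0) next
    expect_equal(row$tree_density, nrow(alive) * per_ha)
    expect_equal(row$tree_dbh_mean, mean(alive$dbh_mm))
    expect_equal(row$dbh_range, diff(range(alive$dbh_mm)))
    expect_equal(row$height_range, diff(range(alive$height_m)))
    expect_equal(row$large_tree_density, sum(alive$dbh_mm > 425) * per_ha)
    expect_equal(row$softwood_large_density,
                 sum(alive$dbh_mm > 425 & alive$wood == "soft") * per_ha)
    expect_equal(row$tree_richness, length(unique(alive$species_code)))
    ba <- pi * (alive$dbh_mm / 2000)^2
    expect_equal(row$basal_area, sum(ba) * per_ha)
    expect_equal(row$wood_density_mean,
                 sum(ba * alive$wood_density_g_cm3) / sum(ba))
    ba_sp <- tapply(ba, alive$species_code, sum)
    expect_equal(row$dominant_species,
                 sort(names(ba_sp)[ba_sp == max(ba_sp)])[1])
    ## invariant chain of the density variables
    expect_lte(row$softwood_large_density, row$large_tree_density)
    expect_lte(row$large_tree_density, row$tree_density)
  }
})

test_that("doubling every tree doubles every density", {
  tr <- mk_trees("P1", c(120, 480, 300), wood = c("soft", "soft", "hard"))
  tr2 <- rbind(tr, tr)
  a <- compute_plot_variables(mk_plot(), tr)
  b <- compute_plot_variables(mk_plot(), tr2)
  for (v in c("tree_density", "large_tree_density", "softwood_large_density",
              "dead_tree_density", "basal_area"))
    expect_equal(b[[v]], 2 * a[[v]])
})

test_that("negative measurements raise a data error naming the plot", {
  expect_error(compute_plot_variables(mk_plot("Pbad"), mk_trees("Pbad", -5)),
               "Pbad")
})

test_that("climate extraction takes the nearest cell and flags misses", {
  plots <- data.frame(plot_id = c("a", "b"), x_m = c(500, 99999),
                      y_m = c(500, 500), stringsAsFactors = FALSE)
  const <- grid_raster(matrix(42, 10, 10), 0, 0, 100)
  out <- extract_climate_to_plots(plots, list(cc = const))
  expect_equal(out$cc, c(42, NA))
  expect_equal(out$climate_complete, c(TRUE, FALSE))
  ## coordinate-scale mismatch (no plot inside the raster) is an interface error
  bad <- grid_raster(matrix(1, 2, 2), 1e7, 1e7, 100)
  expect_error(extract_climate_to_plots(plots, list(x = bad)), "interface error")
})

test_that("correlation screening follows the greedy rule", {
  set.seed(1)
  n <- 200
  a <- rnorm(n)
  d <- data.frame(A = a, B = a + rnorm(n, 0, 0.1), C = rnorm(n))
  ## r(A,B) ~ 0.99, both ~0 with C
  res <- screen_correlated(d, ranking = c("A", "B", "C"))
  expect_equal(res$retained, c("A", "C"))
  expect_match(res$dropped[["B"]], "A")
  ## independent variables all retained
  d2 <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  res2 <- screen_correlated(d2, ranking = names(d2))
  expect_equal(res2$retained, names(d2))
  ## all pairwise |r| below threshold in the output
  cm <- cor(d2[res2$retained])
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.70))
  ## perfect correlation keeps only the higher-ranked variable
  d3 <- data.frame(X = a, Y = 2 * a)
  expect_equal(screen_correlated(d3, c("X", "Y"))$retained, "X")
  ## zero variance drops with a warning
  d4 <- data.frame(K = rep(1, n), L = rnorm(n))
  expect_warning(res4 <- screen_correlated(d4, c("K", "L")), "zero variance")
  expect_equal(res4$retained, "L")
})

test_that("single-variable gain ranking recovers the generating variable", {
  set.seed(5)
  n <- 60; N <- 150
  bg <- data.frame(sig = rnorm(N), noise1 = rnorm(N), noise2 = rnorm(N))
  pres <- data.frame(sig = rnorm(n, mean = 1.5), noise1 = rnorm(n),
                     noise2 = rnorm(n))
  rk <- rank_by_single_variable_gain(pres, bg, c("noise1", "sig", "noise2"),
                                     classes = "L")
  expect_equal(rk$variable[1], "sig")
  ## an uninformative variable has near-zero gain and ranks last or tied-last
  expect_lt(min(rk$gain), 0.05)
  ## duplicated variables get equal gains
  bg$sig2 <- bg$sig; pres$sig2 <- pres$sig
  rk2 <- rank_by_single_variable_gain(pres, bg, c("sig", "sig2"), classes = "L")
  expect_lt(abs(diff(rk2$gain)), 1e-6)
})
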