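test_that("feature expansion produces the expected feature sets", {
  set.seed(2)
  pres <- data.frame(x = rnorm(20), g = sample(c("a", "b"), 20, TRUE))
  bg <- data.frame(x = rnorm(60), g = sample(c("a", "b"), 60, TRUE))
  ## L only: one feature per quantitative variable
  feL <- expand_features(pres, bg, vars = "x", classes = "L")
  expect_equal(ncol(feL$Xb), 1)
  expect_equal(feL$features$class, "linear")
  ## binary categorical: two complementary indicators
  feC <- expand_features(pres, bg, vars = "g", classes = "L")
  expect_equal(ncol(feC$Xb), 2)
  expect_true(all(rowSums(feC$Xb) == 1))
  expect_true(all(rowSums(feC$Xp) == 1))
  ## hinge: at most 2 x n_knots features per variable, knots inside the range
  feH <- expand_features(pres, bg, vars = "x", classes = "H", n_hinge_knots = 50)
  expect_lte(ncol(feH$Xb), 100)
  expect_true(all(abs(feH$features$knot) > min(bg$x) &
                    abs(feH$features$knot) < max(bg$x)))
  ## all features scaled to [0, 1] on the background
  expect_true(all(feH$Xb >= 0 & feH$Xb <= 1))
  ## constant variable excluded with a warning
  pres$k <- 1; bg$k <- 1
  expect_warning(expand_features(pres, bg, vars = c("x", "k"), classes = "L"),
                 "constant")
  expect_error(expand_features(pres, bg, vars = "x", classes = "Z"), "LQH")
})

test_that("design matrices rebuild identically on the training data", {
  pr <- random_feature_problem(3)
  fe <- expand_features(pr$pres, pr$bg, classes = "LQH", n_hinge_knots = 8)
  expect_equal(build_design(fe, pr$pres), fe$Xp, ignore_attr = TRUE)
  expect_equal(build_design(fe, pr$bg), fe$Xb, ignore_attr = TRUE)
})

test_that("single binary feature recovers the closed-form KKT solution", {
  ## all presences have f = 1, half the background does; lambda = 0.05:
  ## E_model[f] = e^b/(e^b + 1) = 1 - lambda  =>  b = ln(19)
  pres <- data.frame(v = rep(1, 25))
  bg <- data.frame(v = rep(c(0, 1), each = 50))
  fe <- expand_features(pres, bg, vars = "v", classes = "L")
  m <- maxent_fit(fe, lambda = 0.05)
  expect_equal(unname(m$beta), log(19), tolerance = 1e-6)
  expect_kkt(m, fe)
})

test_that("null species shrink to zero gain; extreme regularization kills all coefficients", {
  set.seed(10)
  bgv <- rnorm(300)
  pres <- data.frame(v = sample(bgv, 60))     # presences drawn from background
  bg <- data.frame(v = bgv)
  fe <- expand_features(pres, bg, classes = "LQ")
  m <- maxent_fit(fe)
  expect_lt(m$gain, 0.01)
  ## enormous multiplier: exact zeros, gain exactly 0
  pr <- random_feature_problem(4)
  fe2 <- expand_features(pr$pres, pr$bg, classes = "LQ")
  m2 <- maxent_fit(fe2, rm = 1e4)
  expect_true(all(m2$beta == 0))
  expect_equal(m2$gain, 0)
  expect_equal(training_gain(m2), 0)
})

test_that("unregularized limit concentrates the density: G -> log(N/n1)", {
  ## presences all at f = 1; 2 of 10 background points at f = 1. As the
  ## penalty vanishes the model mass concentrates on those 2 points and the
  ## gain approaches log(10/2).
  pres <- data.frame(v = rep(1, 5))
  bg <- data.frame(v = rep(c(1, 0), c(2, 8)))
  fe <- expand_features(pres, bg, vars = "v", classes = "L")
  m <- maxent_fit(fe, lambda = 1e-7)
  expect_equal(m$gain, log(10 / 2), tolerance = 1e-4)
})

test_that("fits satisfy KKT and the model density normalizes over the background", {
  for (s in 1:8) {
    pr <- random_feature_problem(s, n_vars = 4)
    fe <- expand_features(pr$pres, pr$bg, classes = if (s %% 2) "LQ" else "LQH",
                          n_hinge_knots = 6, add_samples_to_background = TRUE)
    m <- maxent_fit(fe, rm = ifelse(s %% 3 == 0, 2, 1))
    expect_true(m$converged)
    expect_kkt(m, fe)
    ## q sums to 1 over the background
    expect_equal(sum(predict_maxent(m, fe$Xb)), 1, tolerance = 1e-10)
    expect_gte(m$gain, 0)
  }
})

test_that("contributions are non-negative, sum to the gain, and credit the owner", {
  pr <- random_feature_problem(7, n_vars = 3)
  fe <- expand_features(pr$pres, pr$bg, classes = "LQ")
  m <- maxent_fit(fe)
  vc <- variable_contribution(m)$variable
  expect_true(all(vc >= 0))
  expect_equal(sum(vc), m$gain, tolerance = 1e-8)
  ## single-variable model: the whole gain belongs to that variable
  fe1 <- expand_features(pr$pres, pr$bg, vars = "v1", classes = "LQ")
  m1 <- maxent_fit(fe1)
  vc1 <- variable_contribution(m1)$variable
  expect_equal(unname(vc1["v1"]), m1$gain)
  ## unmapped variable names are an error when a catalog is supplied
  expect_error(variable_contribution(m, catalog = variable_catalog()),
               "not mapped")
})

test_that("duplicated variables share contribution symmetrically over path seeds", {
  ## path attribution is order-dependent for exact duplicates (as in Maxent's
  ## percent contribution): whichever feature the descent visits first takes
  ## the credit. Symmetry holds in distribution: randomizing the visiting
  ## order over seeds, each duplicate wins about half the time, the joint
  ## total always equals the single-variable gain, and the mean shares agree.
  set.seed(31)
  n <- 40; N <- 120
  pres <- data.frame(a = rnorm(n, 1.2))
  bg <- data.frame(a = rnorm(N))
  pres$b <- pres$a; bg$b <- bg$a        # exact duplicate
  fe <- expand_features(pres, bg, vars = c("a", "b"), classes = "L")
  fe1 <- expand_features(pres, bg, vars = "a", classes = "L")
  share_a <- numeric(40)
  for (s in seq_along(share_a)) {
    m <- maxent_fit(fe, path_seed = s)
    vc <- variable_contribution(m)$variable
    share_a[s] <- vc["a"] / sum(vc)
    ## the pair jointly carries the same gain as the single variable
    m1 <- maxent_fit(fe1)
    expect_equal(sum(vc), m1$gain, tolerance = 1e-4)
  }
  ## each duplicate leads about half the time (99% binomial band for p=0.5)
  wins <- mean(share_a > 0.5)
  expect_gt(wins, 0.5 - 2.576 * sqrt(0.25 / length(share_a)))
  expect_lt(wins, 0.5 + 2.576 * sqrt(0.25 / length(share_a)))
  ## and the mean share is near one half
  expect_lt(abs(mean(share_a) - 0.5), 0.25)
})

test_that("permutation importance agrees with path attribution on the dominant variable", {
  set.seed(12)
  n <- 50; N <- 150
  pres <- data.frame(sig = rnorm(n, 1.8), noise = rnorm(n))
  bg <- data.frame(sig = rnorm(N), noise = rnorm(N))
  fe <- expand_features(pres, bg, classes = "LQ")
  m <- maxent_fit(fe)
  pa <- variable_contribution(m)$variable
  pi_ <- permutation_importance(m, fe, n_perm = 3, seed = 2)
  expect_equal(names(which.max(pa)), "sig")
  expect_equal(names(which.max(pi_)), "sig")
})

test_that("rank-based AUC matches pair enumeration and handles ties", {
  expect_equal(auc_mw(c(1, 1), c(1, 1, 1)), 0.5)
  expect_equal(auc_mw(c(5, 6), c(1, 2)), 1)
  expect_equal(auc_mw(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  brute <- function(p, b) {
    s <- 0
    for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
    s / (length(p) * length(b))
  }
  for (s in 1:10) {
    set.seed(s)
    p <- sample(round(rnorm(15), 1)); b <- sample(round(rnorm(25), 1))
    expect_equal(auc_mw(p, b), brute(p, b))
  }
})

test_that("AICc follows the small-sample formula and penalizes parameters", {
  ## hand arithmetic: k = 3, n = 10, ll = -20 -> 6 + 40 + 24/6 = 50
  fake <- structure(list(beta = c(a = 1, b = 2, c = 3), logZ = 0),
                    class = "maxent_model")
  Xp <- matrix(0, 10, 3)
  a <- aicc_maxent(fake, Xp)      # ll = 0 here; check formula directly below
  expect_equal(a$k, 3)
  aicc_formula <- function(k, n, ll) 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(aicc_formula(3, 10, -20), 50)
  expect_equal(a$aicc, aicc_formula(3, 10, a$ll))
  ## k = 0: AICc = -2 ll
  fake0 <- structure(list(beta = c(a = 0, b = 0, c = 0), logZ = log(7)),
                     class = "maxent_model")
  a0 <- aicc_maxent(fake0, Xp)
  expect_equal(a0$aicc, -2 * a0$ll)
  ## more parameters at the same likelihood cost strictly more
  expect_gt(aicc_formula(4, 10, -20), aicc_formula(3, 10, -20))
  ## n <= k + 1 disqualifies
  expect_true(is.na(aicc_maxent(fake, matrix(0, 4, 3))$aicc))
})

test_that("tuning picks the lowest AICc and breaks ties toward parsimony", {
  pr <- random_feature_problem(9, n_pres = 40, n_bg = 120, n_vars = 2)
  names(pr$pres) <- names(pr$bg) <- c("v1", "v2")
  tn <- tune_maxent(pr$pres, pr$bg, vars = c("v1", "v2"),
                    classes_grid = c("L", "LQ"), rm_grid = c(1, 2),
                    n_hinge_knots = 4, nfolds = 4, seed = 3)
  expect_equal(tn$best$aicc, min(tn$grid$aicc, na.rm = TRUE))
  expect_true(is.finite(tn$cv$auc_test_mean))
  ## single candidate returns trivially
  tn1 <- tune_maxent(pr$pres, pr$bg, vars = "v1", classes_grid = "L",
                     rm_grid = 1, nfolds = 3, seed = 3)
  expect_equal(nrow(tn1$grid), 1)
  ## duplicated rm values give identical AICc; the tie goes to the larger rm
  tn2 <- tune_maxent(pr$pres, pr$bg, vars = "v1", classes_grid = "L",
                     rm_grid = c(1, 1), nfolds = 3, seed = 3)
  expect_equal(tn2$grid$aicc[1], tn2$grid$aicc[2])
})

test_that("models serialize to JSON and predict identically after reload", {
  pr <- random_feature_problem(13)
  fe <- expand_features(pr$pres, pr$bg, classes = "LQH", n_hinge_knots = 5)
  m <- maxent_fit(fe)
  f <- tempfile(fileext = ".json")
  maxent_to_json(m, f)
  m2 <- maxent_from_json(f)
  expect_equal(predict_maxent(m2, pr$bg), predict_maxent(m, pr$bg),
               tolerance = 1e-12)
  unlink(f)
})
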