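## L1-regularized maximum-entropy fit over a background sample.
##
## The model is the Gibbs density q(x) = exp(beta . f(x)) / Z with Z summed
## over the background points. Fitting minimizes
##
##   O(beta) = -(1/n) sum_presence beta.f(x_i) + log sum_bg exp(beta.f(x))
##             + sum_j lambda_j |beta_j|
##
## by cyclic coordinate descent (compiled in src/maxent_cd.cpp). Each
## coordinate subproblem is solved EXACTLY (soft-threshold test at zero,
## then safeguarded Newton/bisection on the smooth part), so the optimum
## satisfies the defining Maxent KKT property
## |E_presence[f_j] - E_model[f_j]| <= lambda_j, with equality for active
## features; convergence is declared only once a full KKT pass holds within
## `kkt_tol`.

#' Fit a presence-background maximum-entropy model
#'
#' @param fe a [expand_features()] object.
#' @param rm regularization multiplier (> 0), scales the default per-feature
#'   penalties.
#' @param lambda optional vector of per-feature L1 penalties overriding the
#'   defaults.
#' @param max_cycles maximum coordinate-descent cycles (default 10000).
#' @param tol convergence tolerance on the objective decrease per cycle.
#' @param kkt_tol tolerance of the final full KKT pass (default 1e-6).
#' @param path_seed optional integer; when given, the coordinate visiting
#'   order is a seeded random permutation instead of the natural feature
#'   order. The optimum is unchanged, but the path attribution of gain among
#'   strongly correlated variables depends on the visiting order, so
#'   randomizing over seeds probes that sensitivity.
#' @return An object of class `maxent_model`: coefficients `beta`, penalties
#'   `lambda`, normalizer `logZ` (over background), training `gain`,
#'   per-variable positive objective improvements `improvements` (the path
#'   attribution record), the feature definitions, and fit diagnostics.
#' @export
maxent_fit <- function(fe, rm = 1, lambda = NULL, max_cycles = 10000,
                       tol = 1e-9, kkt_tol = 1e-6, path_seed = NULL) {
  stopifnot(inherits(fe, "maxent_features"))
  if (rm <= 0) stop_fsd("regularization multiplier must be > 0")
  Xp <- fe$Xp; Xb <- fe$Xb
  if (any(!is.finite(Xp)) || any(!is.finite(Xb)))
    stop_fsd("data error: non-finite feature values")
  n <- nrow(Xp); N <- nrow(Xb); J <- ncol(Xb)
  if (is.null(lambda)) lambda <- default_lambda(fe, rm = rm)
  if (length(lambda) == 1L) lambda <- rep(lambda, J)
  stopifnot(length(lambda) == J, all(lambda > 0))
  Ep <- colMeans(Xp)
  perm <- seq_len(J)
  if (!is.null(path_seed)) {
    set.seed(path_seed)
    perm <- sample.int(J)
  }
  var_index <- match(fe$features$variable, fe$vars) - 1L
  res <- .maxent_cd(Xb[, perm, drop = FALSE], Ep[perm],
                    as.numeric(lambda)[perm], var_index[perm],
                    length(fe$vars), as.integer(max_cycles), tol, kkt_tol, 60)
  if (!res$converged)
    warning(sprintf("maxent_fit: not converged after %d cycles (objective %.8f)",
                    res$cycles, res$objective))
  beta <- numeric(J)
  beta[perm] <- res$beta
  eta <- res$eta
  logZ <- logsumexp(eta)
  gain <- sum(Ep * beta) - logZ + log(N)
  structure(list(
    beta = stats::setNames(beta, fe$features$name), lambda = lambda, rm = rm,
    features = fe$features, transforms = fe$transforms, vars = fe$vars,
    classes = fe$classes, logZ = logZ, n_presence = n, n_background = N,
    gain = gain,
    improvements = stats::setNames(res$improvements, fe$vars),
    eta_background = eta, Ep = Ep,
    converged = res$converged, cycles = res$cycles, objective = res$objective
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d features (%d active), rm = %g, gain = %.4f, n = %d/%d\n",
    length(x$beta), sum(x$beta != 0), x$rm, x$gain, x$n_presence, x$n_background))
  invisible(x)
}

#' Check the Maxent KKT conditions of a fitted model
#'
#' At the optimum, `|E_presence[f_j] - E_model[f_j]| <= lambda_j` for every
#' feature, with equality for active (nonzero) features.
#'
#' @param model a fitted [maxent_fit()] model.
#' @param fe the [expand_features()] object the model was fitted on.
#' @return list with `max_violation` (most positive
#'   `|Ep - Emodel| - lambda` over all features), `max_active_gap` (largest
#'   `|lambda - |Ep - Emodel||` over active features) and the per-feature
#'   table.
#' @export
kkt_check <- function(model, fe) {
  w <- exp(model$eta_background - model$logZ)   # model weights, sum to 1
  Em <- as.numeric(crossprod(fe$Xb, w))
  gap <- abs(model$Ep - Em)
  tab <- data.frame(feature = model$features$name, Ep = model$Ep, Emodel = Em,
                    lambda = model$lambda, active = model$beta != 0,
                    violation = gap - model$lambda, stringsAsFactors = FALSE)
  act <- tab$active
  list(max_violation = max(tab$violation),
       max_active_gap = if (any(act)) max(abs(gap[act] - model$lambda[act])) else 0,
       table = tab)
}

#' Raw Maxent output at new points
#'
#' @param model a fitted [maxent_fit()] model.
#' @param newdata data frame of points holding the model variables, or a
#'   pre-built design matrix.
#' @return Numeric vector of raw outputs `exp(beta . f(x)) / Z`; they sum to
#'   1 over the background sample used in fitting.
#' @export
predict_maxent <- function(model, newdata) {
  X <- if (is.matrix(newdata)) newdata else build_design(model, newdata)
  as.numeric(exp(X %*% model$beta - model$logZ))
}

#' Training gain of a model at presence points
#'
#' `G = (1/n) sum log q(x_i) + log N_background`: the mean log improvement of
#' the fitted density at the presences over a uniform density on the
#' background.
#'
#' @param model a fitted [maxent_fit()] model.
#' @param Xp presence design matrix (defaults to the training presences'
#'   expectation stored in the model).
#' @return Numeric gain (0 for the uniform model).
#' @export
training_gain <- function(model, Xp = NULL) {
  if (is.null(Xp)) return(model$gain)
  mean(Xp %*% model$beta) - model$logZ + log(model$n_background)
}

#' Per-variable and per-group contributions to training gain
#'
#' Path attribution: each coordinate-descent update's objective improvement
#' is credited to the variable owning the updated feature; positive credits
#' are normalized and scaled to the total training gain, so contributions are
#' non-negative and sum to the gain. (The analogue of Maxent's "percent
#' contribution".)
#'
#' @param model a fitted [maxent_fit()] model.
#' @param catalog optional [variable_catalog()]-style data frame mapping
#'   variables to mechanistic groups; when given, per-group sums are added.
#' @return list with `variable` (named numeric vector summing to the gain)
#'   and, when `catalog` is given, `group`.
#' @export
variable_contribution <- function(model, catalog = NULL) {
  imp <- model$improvements
  imp[imp < 0] <- 0
  cv <- if (model$gain <= 0 || sum(imp) <= 0)
    stats::setNames(numeric(length(imp)), names(imp))
  else imp / sum(imp) * model$gain
  out <- list(variable = cv)
  if (!is.null(catalog)) {
    miss <- setdiff(names(cv), catalog$variable)
    if (length(miss))
      stop_fsd("variable(s) not mapped in catalog: %s", paste(miss, collapse = ", "))
    grp <- catalog$group[match(names(cv), catalog$variable)]
    out$group <- tapply(cv, grp, sum)
  }
  out
}

#' Permutation importance of model variables
#'
#' Cross-check estimator for [variable_contribution()]: permutes one
#' variable's values across the pooled presence + background design rows and
#' reports the drop in training gain.
#'
#' @param model a fitted [maxent_fit()] model.
#' @param fe the [expand_features()] object the model was fitted on.
#' @param n_perm permutations per variable (default 5).
#' @param seed integer seed.
#' @return Named numeric vector of mean gain drops (clipped at 0).
#' @export
permutation_importance <- function(model, fe, n_perm = 5, seed = 1L) {
  set.seed(seed)
  base_gain <- model$gain
  out <- stats::setNames(numeric(length(fe$vars)), fe$vars)
  np <- nrow(fe$Xp)
  for (v in fe$vars) {
    jj <- which(fe$features$variable == v)
    drops <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      all_rows <- rbind(fe$Xp[, jj, drop = FALSE], fe$Xb[, jj, drop = FALSE])
      perm <- all_rows[sample.int(nrow(all_rows)), , drop = FALSE]
      Xp2 <- fe$Xp; Xb2 <- fe$Xb
      Xp2[, jj] <- perm[seq_len(np), ]
      Xb2[, jj] <- perm[-seq_len(np), ]
      etab <- as.numeric(Xb2 %*% model$beta)
      lz <- logsumexp(etab)
      g <- mean(Xp2 %*% model$beta) - lz + log(nrow(Xb2))
      drops[p] <- base_gain - g
    }
    out[v] <- max(0, mean(drops))
  }
  out
}

#' Rank-based (Mann-Whitney) AUC with tie correction
#'
#' Probability that a random presence scores above a random background point,
#' counting ties as one half.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in `[0, 1]` (0.5 when all scores are tied).
#' @export
auc_mw <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  stopifnot(np >= 1, nb >= 1)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Small-sample-corrected AIC of a Maxent model
#'
#' `AICc = 2k - 2ll + 2k(k+1)/(n-k-1)` with `ll` the summed log of the raw
#' output (standardized to sum to 1 over the background) at the presences and
#' `k` the number of nonzero coefficients. Undefined (NA) when `n <= k + 1`,
#' which disqualifies the model from tuning.
#'
#' @param model a fitted [maxent_fit()] model.
#' @param Xp presence design matrix (defaults to the training presences).
#' @return list with `aicc`, `ll`, `k`, `n`.
#' @export
aicc_maxent <- function(model, Xp) {
  k <- sum(model$beta != 0)
  n <- nrow(Xp)
  ll <- sum(Xp %*% model$beta - model$logZ)
  aicc <- if (n <= k + 1) NA_real_ else 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
  list(aicc = aicc, ll = ll, k = k, n = n)
}

#' Cross-validated test AUC of a Maxent setting
#'
#' Random partition of the presences into `nfolds` folds (all background
#' points reused in every fold); each fold's model is refitted on the
#' training presences and scored on the held-out presences against the
#' background. The reported AUC_test is the mean over folds.
#'
#' @param fe a [expand_features()] object.
#' @param rm regularization multiplier.
#' @param nfolds number of folds (default 6).
#' @param seed integer seed for the fold split.
#' @return list with `auc_test_mean`, `auc_test_folds`, `auc_train`.
#' @export
cv_auc <- function(fe, rm = 1, nfolds = 6, seed = 1L) {
  n <- nrow(fe$Xp)
  set.seed(seed)
  fold <- sample(rep(seq_len(nfolds), length.out = n))
  aucs <- rep(NA_real_, nfolds)
  for (k in seq_len(nfolds)) {
    test <- fold == k
    if (all(test) || !any(test)) next
    fe_k <- fe
    fe_k$Xp <- fe$Xp[!test, , drop = FALSE]
    m_k <- maxent_fit(fe_k, rm = rm)
    sc_p <- as.numeric(fe$Xp[test, , drop = FALSE] %*% m_k$beta)
    sc_b <- as.numeric(fe$Xb %*% m_k$beta)
    aucs[k] <- auc_mw(sc_p, sc_b)
  }
  full <- maxent_fit(fe, rm = rm)
  list(auc_test_mean = mean(aucs, na.rm = TRUE), auc_test_folds = aucs,
       auc_train = auc_mw(as.numeric(fe$Xp %*% full$beta),
                          as.numeric(fe$Xb %*% full$beta)))
}

#' Tune feature classes and regularization by AICc
#'
#' Evaluates every combination of feature classes and regularization
#' multipliers, keeps models with defined AICc, and selects the lowest AICc;
#' ties go to the larger multiplier (more parsimonious), then to the shorter
#' feature-class string. The winner's 6-fold cross-validated test AUC is
#' reported.
#'
#' @param presences,backgrounds EnvSample data frames.
#' @param vars variables to model.
#' @param classes_grid character vector of feature-class strings
#'   (default `c("L", "LQ", "H", "LQH")`).
#' @param rm_grid regularization multipliers (default `c(1, 1.5, 2, 2.5, 3)`).
#' @param n_hinge_knots hinge knots per direction.
#' @param nfolds cross-validation folds (default 6).
#' @param seed integer seed.
#' @return list with `best_model`, `best` (winning row), `grid` (the full
#'   report), `cv` (the winner's [cv_auc()] result).
#' @export
tune_maxent <- function(presences, backgrounds, vars,
                        classes_grid = c("L", "LQ", "H", "LQH"),
                        rm_grid = c(1, 1.5, 2, 2.5, 3),
                        n_hinge_knots = 50, nfolds = 6, seed = 1L,
                        add_samples_to_background = FALSE) {
  grid <- expand.grid(classes = classes_grid, rm = rm_grid,
                      stringsAsFactors = FALSE)
  grid$aicc <- NA_real_; grid$k <- NA_integer_; grid$gain <- NA_real_
  fits <- vector("list", nrow(grid))
  fes <- list()
  for (i in seq_len(nrow(grid))) {
    cl <- grid$classes[i]
    fe <- fes[[cl]]
    if (is.null(fe)) {
      fe <- expand_features(presences, backgrounds, vars = vars, classes = cl,
                            n_hinge_knots = n_hinge_knots,
                            add_samples_to_background = add_samples_to_background)
      fes[[cl]] <- fe
    }
    m <- tryCatch(maxent_fit(fe, rm = grid$rm[i]), error = function(e) NULL)
    if (is.null(m)) next
    a <- aicc_maxent(m, fe$Xp)
    grid$aicc[i] <- a$aicc; grid$k[i] <- a$k; grid$gain[i] <- m$gain
    fits[[i]] <- m
  }
  ok <- which(!is.na(grid$aicc))
  if (!length(ok)) stop_fsd("pipeline error: all tuning candidates disqualified")
  ord <- ok[order(grid$aicc[ok], -grid$rm[ok], nchar(grid$classes[ok]))]
  win <- ord[1]
  cv <- cv_auc(fes[[grid$classes[win]]], rm = grid$rm[win], nfolds = nfolds,
               seed = seed)
  list(best_model = fits[[win]], best = grid[win, , drop = FALSE],
       grid = grid, cv = cv)
}

#' Serialize / restore a Maxent model as JSON
#'
#' Flat JSON document holding feature definitions, scaling constants,
#' coefficients, penalties and the normalizer, sufficient to rebuild
#' predictions with [predict_maxent()].
#'
#' @param model a fitted [maxent_fit()] model.
#' @param path output file path.
#' @return `maxent_to_json` returns `path` invisibly; `maxent_from_json`
#'   returns a reduced `maxent_model` usable for prediction.
#' @export
maxent_to_json <- function(model, path) {
  doc <- list(
    features = model$features, beta = as.numeric(model$beta),
    lambda = as.numeric(model$lambda), rm = model$rm,
    transforms = model$transforms, logZ = model$logZ,
    n_presence = model$n_presence, n_background = model$n_background,
    gain = model$gain, classes = model$classes
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname maxent_to_json
#' @export
maxent_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- lapply(doc$transforms, function(t) t)
  m <- list(features = as.data.frame(doc$features), beta = doc$beta,
            lambda = doc$lambda, rm = doc$rm, transforms = tr, logZ = doc$logZ,
            n_presence = doc$n_presence, n_background = doc$n_background,
            gain = doc$gain, classes = doc$classes)
  m$beta <- stats::setNames(m$beta, m$features$name)
  class(m) <- "maxent_model"
  m
}
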