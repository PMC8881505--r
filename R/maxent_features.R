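## Feature expansion for the presence-background maximum-entropy model.
## All features are scaled to [0, 1] over the background sample; scaling
## constants computed on the background are reused for the presences (values
## outside the background range are clamped).

#' Expand environmental variables into Maxent features
#'
#' Builds linear (`L`), quadratic (`Q`) and hinge (`H`) features for
#' quantitative variables, and one indicator feature per observed level for
#' categorical variables (factor or character columns). Hinge knots sit at
#' background quantiles strictly inside the variable range, in both
#' directions; duplicate or degenerate knots are dropped. Variables constant
#' over the background are excluded with a warning.
#'
#' @param presences,backgrounds data frames holding the variables at presence
#'   and background points.
#' @param vars character vector of variable names to expand; defaults to all
#'   shared columns that are not EnvSample bookkeeping columns.
#' @param classes feature classes as a string subset of `"LQH"` (e.g. `"LQ"`).
#' @param n_hinge_knots hinge knots per direction (default 50).
#' @param add_samples_to_background append the presence rows to the
#'   background (the standard Maxent default); this keeps the presence
#'   feature distribution inside the background's support and prevents
#'   quasi-separation when presences lie outside the sampled background
#'   range. The scaling constants are then computed on the combined set.
#' @return list of class `maxent_features`: design matrices `Xp`, `Xb`
#'   (rows = points, columns = features, values in `[0, 1]`) and a feature
#'   table `features` (`variable`, `class`, `knot`, `level`).
#' @export
expand_features <- function(presences, backgrounds, vars = NULL,
                            classes = "LQH", n_hinge_knots = 50,
                            add_samples_to_background = FALSE) {
  reserved <- c("label", "x_m", "y_m", "n_plots_used", "mean_plot_distance_m",
                "climate_complete")
  if (is.null(vars))
    vars <- setdiff(intersect(names(presences), names(backgrounds)), reserved)
  stopifnot(length(vars) > 0, all(vars %in% names(presences)),
            all(vars %in% names(backgrounds)))
  cls <- strsplit(toupper(classes), "")[[1]]
  if (!length(cls) || !all(cls %in% c("L", "Q", "H")))
    stop_fsd("classes must be a non-empty subset of 'LQH' (got '%s')", classes)
  if (isTRUE(add_samples_to_background))
    backgrounds <- rbind(backgrounds[, vars, drop = FALSE],
                         presences[, vars, drop = FALSE])

  cols_p <- list(); cols_b <- list()
  meta <- list()
  transforms <- list()
  add <- function(p, b, variable, class, knot = NA_real_, dir = NA_character_,
                  level = NA_character_) {
    if (stats::var(b) <= 0) return(invisible(NULL))  # uninformative on background
    k <- length(cols_p) + 1L
    cols_p[[k]] <<- pmin(1, pmax(0, p))
    cols_b[[k]] <<- pmin(1, pmax(0, b))
    meta[[k]] <<- data.frame(variable = variable, class = class, knot = knot,
                             dir = dir, level = level, stringsAsFactors = FALSE)
  }

  for (v in vars) {
    xb <- backgrounds[[v]]; xp <- presences[[v]]
    if (any(!is.finite(xb) & !is.na(xb)) || any(!is.finite(xp) & !is.na(xp)))
      if (is.numeric(xb)) stop_fsd("data error: non-finite values in variable '%s'", v)
    if (is.numeric(xb)) {
      mn <- min(xb); mx <- max(xb)
      if (mx - mn <= 0) {
        warning(sprintf("variable '%s' is constant over the background; excluded", v))
        next
      }
      mn2 <- min(xb^2); mx2 <- max(xb^2)
      transforms[[v]] <- list(type = "quantitative", mn = mn, mx = mx,
                              mn2 = mn2, mx2 = mx2)
      if ("L" %in% cls)
        add((xp - mn) / (mx - mn), (xb - mn) / (mx - mn), v, "linear")
      if ("Q" %in% cls)
        add((xp^2 - mn2) / (mx2 - mn2), (xb^2 - mn2) / (mx2 - mn2), v, "quadratic")
      if ("H" %in% cls) {
        probs <- seq_len(n_hinge_knots) / (n_hinge_knots + 1)
        knots <- unique(as.numeric(stats::quantile(xb, probs, type = 7)))
        knots <- knots[knots > mn & knots < mx]
        for (k in knots) {
          add(pmax(0, (xp - k) / (mx - k)), pmax(0, (xb - k) / (mx - k)),
              v, "hinge", knot = k, dir = "fwd")
          add(pmax(0, (k - xp) / (k - mn)), pmax(0, (k - xb) / (k - mn)),
              v, "hinge", knot = k, dir = "rev")
        }
      }
    } else {
      lev <- sort(unique(c(as.character(xb), as.character(xp))))
      transforms[[v]] <- list(type = "categorical", levels = lev)
      for (L in lev)
        add(as.numeric(as.character(xp) == L), as.numeric(as.character(xb) == L),
            v, "categorical", level = L)
    }
  }
  if (!length(cols_p))
    stop_fsd("no usable features: all variables constant or missing")
  Xp <- do.call(cbind, cols_p); Xb <- do.call(cbind, cols_b)
  features <- do.call(rbind, meta)
  features$name <- paste0(
    features$variable, ".", features$class,
    ifelse(is.na(features$knot), "",
           sprintf("_%s@%.6g", features$dir, features$knot)),
    ifelse(is.na(features$level), "", paste0(":", features$level)))
  colnames(Xp) <- colnames(Xb) <- features$name
  structure(list(Xp = Xp, Xb = Xb, features = features, transforms = transforms,
                 vars = unique(features$variable), classes = classes,
                 n_hinge_knots = n_hinge_knots),
            class = "maxent_features")
}

#' Apply a fitted feature expansion to new data
#'
#' Rebuilds the design matrix for new points using the scaling constants,
#' hinge knots and categorical levels fixed on the original background
#' sample. Values outside the background range are clamped to `[0, 1]`.
#'
#' @param fe a `maxent_features` object (or the `features` slot of a fitted
#'   model).
#' @param newdata data frame holding the model variables.
#' @return Numeric design matrix with one column per feature.
#' @export
build_design <- function(fe, newdata) {
  ft <- fe$features
  X <- matrix(0, nrow(newdata), nrow(ft))
  for (j in seq_len(nrow(ft))) {
    v <- ft$variable[j]
    if (!v %in% names(newdata)) stop_fsd("newdata lacks variable '%s'", v)
    tr <- fe$transforms[[v]]
    x <- newdata[[v]]
    col <- switch(ft$class[j],
      linear = (x - tr$mn) / (tr$mx - tr$mn),
      quadratic = (x^2 - tr$mn2) / (tr$mx2 - tr$mn2),
      hinge = if (identical(ft$dir[j], "fwd")) {
        k <- ft$knot[j]; pmax(0, (x - k) / (tr$mx - k))
      } else {
        k <- ft$knot[j]; pmax(0, (k - x) / (k - tr$mn))
      },
      categorical = as.numeric(as.character(x) == ft$level[j]))
    X[, j] <- pmin(1, pmax(0, col))
  }
  colnames(X) <- ft$name
  X
}

## Published Maxent default regularization: lambda_j = rm * beta_class(n) *
## sd_j(presences) / sqrt(n), with the class base values interpolated over
## presence sample size. The presence standard deviation is floored to keep
## penalties strictly positive for presence-constant features.
default_lambda <- function(fe, rm = 1, sd_floor = 0.05) {
  n <- nrow(fe$Xp)
  b_lq <- stats::approx(c(10, 30, 100), c(1.0, 0.2, 0.05), xout = n, rule = 2)$y
  b_cat <- stats::approx(c(0, 10, 17), c(0.65, 0.5, 0.25), xout = n, rule = 2)$y
  base <- c(linear = b_lq, quadratic = b_lq, hinge = 0.5, categorical = b_cat)
  s <- apply(fe$Xp, 2, stats::sd)
  s <- pmax(s, sd_floor)
  rm * base[fe$features$class] * s / sqrt(n)
}
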