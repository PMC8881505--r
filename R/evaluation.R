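## Null-model calibration of discrimination ability: the observed model's
## cross-validated test AUC is compared against models fitted to random
## presence sets of the same size, run through the identical downstream
## pipeline (background generation, interpolation, modelling).

#' Run null models for a species
#'
#' Each replicate draws `n_presences` uniform random points in the region
#' (optionally restricted to forested land), runs the supplied pipeline
#' function on them, and records the resulting test AUC. The observed AUC is
#' compared to the empirical 5th-95th percentile band (type-7 interpolation);
#' the model is "better than random" when the observed AUC exceeds the 95th
#' percentile.
#'
#' @param pipeline_fn function(presences_xy, seed) returning a list with at
#'   least `auc_test` — the same procedure used for the observed data.
#' @param n_presences number of random presences per replicate.
#' @param region extent `c(xmin, xmax, ymin, ymax)` (m).
#' @param observed_auc the observed model's test AUC.
#' @param n_reps number of replicates (default 100).
#' @param seed integer master seed; replicate `i` uses `seed + i`.
#' @param forest_mask optional binary [grid_raster()]; when given, null
#'   presences are drawn only on forested cells.
#' @return list of class `null_model_report`: `null_auc` (completed
#'   replicates), `ci` (5th/95th percentiles), `observed_auc`,
#'   `better_than_random`, `n_reps_requested`, `n_reps_completed`,
#'   `failures` (messages of skipped replicates).
#' @export
run_null_models <- function(pipeline_fn, n_presences, region, observed_auc,
                            n_reps = 100, seed = 1L, forest_mask = NULL) {
  stopifnot(is.function(pipeline_fn), n_presences >= 1, n_reps >= 1)
  null_auc <- rep(NA_real_, n_reps)
  failures <- character(0)
  for (i in seq_len(n_reps)) {
    rep_seed <- seed + i
    set.seed(rep_seed)
    if (is.null(forest_mask)) {
      pts <- data.frame(x_m = stats::runif(n_presences, region[1], region[2]),
                        y_m = stats::runif(n_presences, region[3], region[4]))
    } else {
      ## rejection-sample onto forested cells
      pts <- data.frame(x_m = numeric(0), y_m = numeric(0))
      tries <- 0L
      while (nrow(pts) < n_presences && tries < 200L) {
        cand <- data.frame(x_m = stats::runif(4 * n_presences, region[1], region[2]),
                           y_m = stats::runif(4 * n_presences, region[3], region[4]))
        hit <- raster_extract(forest_mask, cand$x_m, cand$y_m) == 1
        pts <- rbind(pts, cand[which(hit), , drop = FALSE])
        tries <- tries + 1L
      }
      if (nrow(pts) < n_presences)
        stop_fsd("null presences: forest mask too sparse to place points")
      pts <- pts[seq_len(n_presences), , drop = FALSE]
    }
    res <- tryCatch(pipeline_fn(pts, seed = rep_seed), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("rep %d: %s", i, conditionMessage(res)))
      next
    }
    null_auc[i] <- res$auc_test
  }
  done <- null_auc[!is.na(null_auc)]
  if (!length(done)) stop_fsd("all null replicates failed")
  ci <- stats::quantile(done, c(0.05, 0.95), type = 7, names = FALSE)
  structure(list(
    null_auc = done, ci = c(lower = ci[1], upper = ci[2]),
    observed_auc = observed_auc,
    better_than_random = observed_auc > ci[2],
    n_reps_requested = n_reps, n_reps_completed = length(done),
    failures = failures
  ), class = "null_model_report")
}

#' @export
print.null_model_report <- function(x, ...) {
  cat(sprintf(
    "null models: %d/%d replicates, null AUC CI [%.3f, %.3f], observed %.3f -> %s\n",
    x$n_reps_completed, x$n_reps_requested, x$ci[1], x$ci[2], x$observed_auc,
    if (x$better_than_random) "better than random" else "not better than random"))
  invisible(x)
}
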