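## Trait-level meta-analysis: relating per-species model training gains
## (total, per mechanistic group, per variable) to roosting ecology and
## flight morphology.

trait_result <- function(label, F, df1, df2, r2, p, p_adj = NA_real_,
                         overflow = FALSE, note = NA_character_) {
  structure(list(label = label, F = F, df1 = df1, df2 = df2, r2 = r2, p = p,
                 p_adj = p_adj, overflow = overflow, note = note),
            class = "trait_test_result")
}

#' @export
print.trait_test_result <- function(x, ...) {
  cat(sprintf("%s: F(%d,%d) = %s, R2 = %.3f, p = %.4g%s\n", x$label,
              x$df1, x$df2,
              if (x$overflow) "overflow (zero within-group variance)" else
                sprintf("%.3f", x$F),
              x$r2, x$p,
              if (!is.na(x$p_adj)) sprintf(", p_adj = %.4g", x$p_adj) else ""))
  invisible(x)
}

#' Linear model of a gain component on a trait with a record-count covariate
#'
#' Fits `response ~ trait + covariate` by least squares and reports the
#' overall model F (df 2, n-3 for a quantitative or two-level trait), R^2,
#' the overall p, and the trait's partial t-test p-value. The number of
#' occurrence records enters as a covariate because it can affect model
#' performance.
#'
#' @param profiles data frame of species gain profiles.
#' @param response name of the gain column to explain.
#' @param trait name of the trait column (numeric, or a two-level factor).
#' @param covariate name of the covariate column (default `"n_records"`).
#' @return A `trait_test_result` with extra fields `p_trait`, `p_covariate`.
#' @export
lm_gain_on_trait <- function(profiles, response, trait, covariate = "n_records") {
  stopifnot(all(c(response, trait, covariate) %in% names(profiles)))
  y <- profiles[[response]]
  n <- length(y)
  lbl <- sprintf("%s ~ %s + %s", response, trait, covariate)
  if (stats::var(y) == 0) {
    out <- trait_result(lbl, 0, 2L, n - 3L, 0, 1)
    out$p_trait <- 1; out$p_covariate <- 1
    return(out)
  }
  tr <- profiles[[trait]]
  if (is.character(tr)) tr <- factor(tr)
  dat <- data.frame(y = y, tr = tr, cov = profiles[[covariate]])
  fit <- stats::lm(y ~ tr + cov, data = dat)
  sm <- summary(fit)
  note <- NA_character_
  co <- sm$coefficients
  tr_rows <- grep("^tr", rownames(co))
  cov_row <- grep("^cov", rownames(co))
  if (any(is.na(stats::coef(fit)))) note <- "collinear trait/covariate; partial p unreliable"
  fs <- sm$fstatistic
  out <- trait_result(lbl, unname(fs[1]), as.integer(fs[2]), as.integer(fs[3]),
                      sm$r.squared,
                      stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
                      note = note)
  out$p_trait <- if (length(tr_rows)) min(co[tr_rows, 4]) else NA_real_
  out$p_covariate <- if (length(cov_row)) co[cov_row, 4] else NA_real_
  out
}

#' One-way ANOVA between two groups of raw values
#'
#' @param values numeric response values.
#' @param groups grouping vector with exactly two levels, each with n >= 2.
#' @param label test label.
#' @return A `trait_test_result` with F (df 1, n-2), `R^2 = SSB/SST` and the
#'   p-value from the F distribution; zero within-group variance is reported
#'   as an overflow flag, never a number.
#' @export
anova_two_group <- function(values, groups, label = "two-group ANOVA") {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop_fsd("anova_two_group requires exactly 2 groups")
  if (any(table(groups) < 2)) stop_fsd("each group needs n >= 2")
  n <- length(values)
  fit <- stats::lm(values ~ groups)
  an <- stats::anova(fit)
  ssb <- an$`Sum Sq`[1]; ssw <- an$`Sum Sq`[2]
  r2 <- ssb / (ssb + ssw)
  if (ssw <= 1e-12 * (ssb + ssw))
    return(trait_result(label, Inf, 1L, n - 2L, r2, 0, overflow = TRUE))
  trait_result(label, an$`F value`[1], 1L, n - 2L, r2, an$`Pr(>F)`[1])
}

#' One-way two-group ANOVA from printed summary statistics
#'
#' Reconstructs the F statistic from group means, standard deviations and
#' sizes: `SSB = n1 (m1 - g)^2 + n2 (m2 - g)^2` with the grand mean `g`, and
#' `MSW = ((n1 - 1) s1^2 + (n2 - 1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @param label test label.
#' @return A `trait_test_result` with F at df (1, n1 + n2 - 2).
#' @export
anova_from_summary <- function(m1, s1, n1, m2, s2, n2,
                               label = "summary ANOVA") {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  g <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - g)^2 + n2 * (m2 - g)^2
  msw <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  df2 <- n1 + n2 - 2L
  ssw <- msw * df2
  r2 <- if (ssb + ssw > 0) ssb / (ssb + ssw) else 0
  if (msw <= 1e-12 * (ssb + ssw))
    return(trait_result(label, Inf, 1L, df2, r2, 0, overflow = TRUE))
  F <- ssb / msw
  trait_result(label, F, 1L, df2, r2,
               stats::pf(F, 1, df2, lower.tail = FALSE))
}

#' Holm step-down adjustment of p-values
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order (via `stats::p.adjust`).
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

#' Group sums and relative shares of per-variable training gain
#'
#' @param gains named numeric vector of per-variable gain contributions.
#' @param catalog [variable_catalog()]-style mapping; every gained variable
#'   must be mapped.
#' @return data.frame with `group`, `gain`, `share_pct`.
#' @export
gain_by_group <- function(gains, catalog = variable_catalog()) {
  miss <- setdiff(names(gains), catalog$variable)
  if (length(miss))
    stop_fsd("variable(s) not mapped in catalog: %s", paste(miss, collapse = ", "))
  grp <- catalog$group[match(names(gains), catalog$variable)]
  g <- tapply(as.numeric(gains), grp, sum)
  total <- sum(g)
  data.frame(group = names(g), gain = as.numeric(g),
             share_pct = if (total > 0) 100 * as.numeric(g) / total else
               rep(0, length(g)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tidy a list of trait test results
#'
#' @param results list of `trait_test_result` objects.
#' @param holm apply Holm correction across the listed tests.
#' @return data.frame: `test`, `F`, `df1`, `df2`, `R2`, `p`, `p_adj`,
#'   `overflow`.
#' @export
trait_results_table <- function(results, holm = TRUE) {
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(test = r$label, F = r$F, df1 = r$df1, df2 = r$df2, R2 = r$r2,
               p = r$p, p_adj = r$p_adj, overflow = r$overflow,
               stringsAsFactors = FALSE)))
  if (holm) tab$p_adj <- holm_adjust(tab$p)
  rownames(tab) <- NULL
  tab
}
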