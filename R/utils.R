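#' @keywords internal
#' @useDynLib forestsdm, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a text tag
#'
#' Stage- and species-level randomness is seeded from a stable polynomial
#' hash of a tag combined with the master seed, so adding a species or stage
#' never perturbs another's random stream.
#'
#' @param master integer master seed.
#' @param tag character tag (e.g. `"background/Mbec"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1000000007
  as.integer((h + (as.numeric(master) %% 2147483647) * 7919) %% 2147483647)
}

## log(sum(exp(x))) with the usual max shift
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## statistical mode; ties broken by `pref` order (first match wins)
mode_stat <- function(x, pref = NULL) {
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L && !is.null(pref)) {
    hit <- as.character(pref)[as.character(pref) %in% top]
    if (length(hit)) return(hit[1L])
  }
  sort(top)[1L]
}

## pairwise Euclidean distances between rows of two xy matrices
xy_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

stop_fsd <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
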