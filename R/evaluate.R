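#' Pearson correlation between recorded and reconstructed series
#'
#' Standard product-moment correlation; returns `NA` (flagged `undefined`)
#' when either input is constant, so callers can exclude and count such
#' pairs.
#'
#' @param x,y numeric series of equal length >= 3.
#' @return correlation coefficient in `[-1, 1]`, or flagged `NA`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("series must have length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, undefined = TRUE))
  stats::cor(x, y)
}

#' Correlation between recorded and reconstructed timings
#'
#' Pearson correlation over paired defined timings; pairs with an undefined
#' (NA) member are dropped and their count reported as attribute
#' `n_dropped`.
#'
#' @param recorded,reconstructed paired timing vectors (ms, `NA` allowed).
#' @return correlation `R` with attribute `n_dropped`.
#' @export
timing_correlation <- function(recorded, reconstructed) {
  if (length(recorded) != length(reconstructed)) stop("timings must be paired")
  ok <- !is.na(recorded) & !is.na(reconstructed)
  if (sum(ok) < 3L) stop("fewer than 3 defined timing pairs")
  structure(pearson_cc(recorded[ok], reconstructed[ok]),
            n_dropped = sum(!ok))
}

#' Wilcoxon tests for paired and unpaired comparisons
#'
#' Thin wrappers around [stats::wilcox.test()] returning the two-sided
#' p-value: the signed-rank test for paired measurements (exact for up to 25
#' nonzero differences without ties, normal approximation with tie/continuity
#' correction otherwise) and the rank-sum test for unpaired groups.
#'
#' @param a,b numeric vectors (paired for the signed-rank test).
#' @return two-sided p-value; flagged `NA` when all paired differences are
#'   zero.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0L) return(structure(NA_real_, undefined = TRUE))
  if (nz < 5L) warning("fewer than 5 nonzero differences; test has little power")
  exact <- nz <= 25L && !any(duplicated(abs(d[d != 0]))) && all(d != 0)
  suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE)$p.value)
}

#' @rdname wilcoxon_signed_rank
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) stop("both groups need n >= 3")
  exact <- length(a) + length(b) <= 50L && !any(duplicated(c(a, b)))
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  if (!is.finite(p)) {
    warning("degenerate rank-sum comparison (complete ties); returning p = 1")
    p <- 1
  }
  p
}
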