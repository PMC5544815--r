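#' Concatenate simulated beats into a potential ensemble
#'
#' Stacks the per-node voltage series of several simulated beats column-wise
#' into a single potential matrix (nodes x beats*steps), the input of the
#' spatial singular value decomposition.
#'
#' @param beats list of [simulate_beat()] results sharing mesh and dt.
#' @return Object of class `potential_ensemble`: list with `phi` (matrix,
#'   mV), `beat_boundaries` (first column of each beat), `origins`, `model`,
#'   `dt`.
#' @export
assemble_ensemble <- function(beats) {
  if (length(beats) == 0L) stop("no beats supplied")
  n_nodes <- vapply(beats, function(b) nrow(b$phi_H), integer(1))
  if (length(unique(n_nodes)) != 1L)
    stop("shape error: beats have mismatched node counts")
  dts <- vapply(beats, function(b) b$dt, numeric(1))
  if (length(unique(dts)) != 1L) stop("shape error: beats have mismatched dt")
  steps <- vapply(beats, function(b) ncol(b$phi_H), integer(1))
  phi <- do.call(cbind, lapply(beats, function(b) b$phi_H))
  structure(list(phi = phi,
                 beat_boundaries = cumsum(c(1L, steps[-length(steps)])),
                 origins = vapply(beats, function(b) b$origin, integer(1)),
                 model = beats[[1]]$model, dt = dts[1]),
            class = "potential_ensemble")
}

#' @export
print.potential_ensemble <- function(x, ...) {
  cat(sprintf("potential ensemble: %d nodes x %d columns (%d beats, model %s)\n",
              nrow(x$phi), ncol(x$phi), length(x$origins), x$model))
  invisible(x)
}

#' Singular value decomposition of a potential ensemble
#'
#' Thin SVD `Phi_H = U D V^T` computed through the Gram matrix of the smaller
#' dimension, which keeps the decomposition of a nodes x (beats*steps) matrix
#' tractable (the Gram side is only nodes x nodes). Singular values are
#' returned in non-increasing order. The sign of each singular vector pair is
#' fixed so that the largest-magnitude entry of each column of `U` is
#' positive, making outputs reproducible across linear-algebra backends.
#'
#' @param x a [assemble_ensemble()] result or a numeric matrix.
#' @param with_v compute the right singular vectors (temporal basis)? They are
#'   diagnostic only and can be large; default `TRUE`.
#' @return list with `u` (n x r), `d` (length r, non-increasing), `v`
#'   ((beats*steps) x r or `NULL`).
#' @export
compute_svd <- function(x, with_v = TRUE) {
  m <- if (inherits(x, "potential_ensemble")) x$phi else as.matrix(x)
  if (length(m) == 0L) stop("empty ensemble")
  if (any(!is.finite(m))) stop("numerical error: non-finite entries")
  if (nrow(m) <= ncol(m)) {
    eg <- eigen(tcrossprod(m), symmetric = TRUE)
    d <- sqrt(pmax(eg$values, 0))
    u <- eg$vectors
    u <- fix_svd_signs(u)
    v <- NULL
    if (with_v) {
      pos <- d > max(d) * 1e-12
      v <- matrix(0, ncol(m), length(d))
      v[, pos] <- crossprod(m, u[, pos, drop = FALSE]) %*%
        diag(1 / d[pos], sum(pos))
    }
    list(u = u, d = d, v = v)
  } else {
    eg <- eigen(crossprod(m), symmetric = TRUE)
    d <- sqrt(pmax(eg$values, 0))
    v <- eg$vectors
    pos <- d > max(d) * 1e-12
    u <- matrix(0, nrow(m), length(d))
    u[, pos] <- m %*% v[, pos, drop = FALSE] %*% diag(1 / d[pos], sum(pos))
    sg <- svd_sign_vector(u)
    u <- sweep(u, 2L, sg, "*")
    v <- sweep(v, 2L, sg, "*")
    if (!with_v) v <- NULL
    list(u = u, d = d, v = v)
  }
}

svd_sign_vector <- function(u) {
  apply(u, 2L, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
}

fix_svd_signs <- function(u) sweep(u, 2L, svd_sign_vector(u), "*")

#' Truncate a spatial SVD basis to a component range
#'
#' Keeps singular components `first` to `last` (1-based component numbering).
#' The default range 2-10 retains nine spatial patterns and drops the first
#' component, which for resting-offset action potentials is a near-constant
#' negative pattern that plays no role when zero-mean electrograms are
#' reconstructed.
#'
#' @param svd_or_u a [compute_svd()] result, or a matrix `U` (then supply `d`).
#' @param d singular values when `svd_or_u` is a plain matrix.
#' @param first,last 1-based component range (defaults 2 and 10).
#' @return Object of class `spatial_basis`: list with `U_k` (n x k,
#'   orthonormal columns), `d` (retained singular values), `range`.
#' @export
truncate_basis <- function(svd_or_u, d = NULL, first = 2L, last = 10L) {
  if (is.list(svd_or_u)) {
    u <- svd_or_u$u
    d <- svd_or_u$d
  } else {
    u <- as.matrix(svd_or_u)
    if (is.null(d)) stop("supply singular values d with a plain U matrix")
  }
  if (first < 1L || first > last) stop("range error: need 1 <= first <= last")
  # Gram-based singular values have a noise floor near sqrt(eps) * d[1]
  rank <- sum(d > max(d) * 1e-7)
  if (last > rank) stop("range error: last = ", last, " exceeds rank ", rank)
  structure(list(U_k = u[, first:last, drop = FALSE], d = d[first:last],
                 range = c(first = as.integer(first), last = as.integer(last))),
            class = "spatial_basis")
}

#' @export
print.spatial_basis <- function(x, ...) {
  cat(sprintf("spatial basis: %d nodes x %d components (components %d-%d)\n",
              nrow(x$U_k), ncol(x$U_k), x$range[1], x$range[2]))
  invisible(x)
}

# Incremental Gram accumulation for large ensembles: U and d of the ensemble
# equal the eigenvectors / sqrt-eigenvalues of sum_b beat_b beat_b^T.
gram_accumulate <- function(gram, beat_matrix) {
  if (is.null(gram)) tcrossprod(beat_matrix) else gram + tcrossprod(beat_matrix)
}

basis_from_gram <- function(gram, first = 2L, last = 10L) {
  eg <- eigen(gram, symmetric = TRUE)
  d <- sqrt(pmax(eg$values, 0))
  u <- fix_svd_signs(eg$vectors)
  truncate_basis(list(u = u, d = d), first = first, last = last)
}
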