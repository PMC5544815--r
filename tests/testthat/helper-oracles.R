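# Independent brute-force oracles used to validate the package's solvers.
# These deliberately avoid the code paths they check.

# exhaustive nearest-vertex search
bf_nearest <- function(points, vertices) {
  apply(points, 1L, function(p) {
    which.min(colSums((t(vertices) - p)^2))
  })
}

# Euclidean projection onto the L1 ball of radius t (Duchi et al.)
proj_l1 <- function(v, t) {
  if (sum(abs(v)) <= t) return(v)
  u <- sort(abs(v), decreasing = TRUE)
  sv <- cumsum(u)
  rho <- max(which(u > (sv - t) / seq_along(u)))
  theta <- (sv[rho] - t) / rho
  sign(v) * pmax(abs(v) - theta, 0)
}

# constrained lasso by projected gradient descent (independent minimizer)
bf_lasso <- function(X, y, budget, iters = 50000L) {
  L <- max(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values)
  b <- numeric(ncol(X))
  step <- 1 / L
  for (i in seq_len(iters)) {
    g <- crossprod(X, X %*% b - y)
    b_new <- proj_l1(b - step * g, budget)
    if (max(abs(b_new - b)) < 1e-14) { b <- b_new; break }
    b <- b_new
  }
  drop(b)
}

# quadratic minimizer by steepest descent with exact line search
# (independent of the closed-form normal-equations solve)
bf_quadratic_min <- function(H, g, iters = 20000L, tol = 1e-15) {
  x <- numeric(length(g))
  for (i in seq_len(iters)) {
    r <- g - H %*% x
    denom <- drop(crossprod(r, H %*% r))
    if (denom <= 0) break
    alpha <- drop(crossprod(r)) / denom
    x <- x + alpha * r
    if (sqrt(sum(r^2)) < tol * max(1, sqrt(sum(g^2)))) break
  }
  drop(x)
}

# exact two-sided p of the signed-rank test by enumeration over sign flips
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ew <- n * (n + 1) / 4
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[signs == 1])
  }, numeric(1))
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-12)
}

# exact two-sided p of the rank-sum test by enumeration over group assignments
bf_rank_sum_p <- function(a, b) {
  pool <- c(a, b)
  r <- rank(pool)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  ew <- na * (length(pool) + 1) / 2
  combs <- utils::combn(length(pool), na)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]))
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-12)
}
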