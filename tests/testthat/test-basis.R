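fake_beat <- function(phi, dt = 1, origin = 1L) {
  structure(list(phi_H = phi, origin = origin, model = "fhn", dt = dt),
            class = "simulated_beat")
}

test_that("ensemble assembly concatenates beats column-wise", {
  set.seed(1)
  beats <- lapply(1:3, function(i) fake_beat(matrix(rnorm(5 * 4), 5), origin = i))
  ens <- assemble_ensemble(beats)
  expect_equal(dim(ens$phi), c(5, 12))
  expect_equal(ens$phi[, 5:8], beats[[2]]$phi_H)
  expect_equal(ens$beat_boundaries, c(1L, 5L, 9L))
  one <- assemble_ensemble(beats[1])
  expect_equal(one$phi, beats[[1]]$phi_H)
  bad <- c(beats, list(fake_beat(matrix(0, 6, 4))))
  expect_error(assemble_ensemble(bad), "shape error")
})

test_that("SVD recovers rank structure and known singular values", {
  u <- c(1, 2, 3, 4); v <- c(2, -1, 1)
  s <- compute_svd(u %*% t(v))
  expect_equal(sum(s$d > 1e-6 * s$d[1]), 1)
  expect_equal(abs(cor(s$u[, 1], u)), 1, tolerance = 1e-12)
  m <- cbind(diag(c(1, 2, 3)), matrix(0, 3, 5))
  expect_equal(compute_svd(m)$d[1:3], c(3, 2, 1))
})

test_that("SVD reconstructs exactly and satisfies the truncation energy identity", {
  set.seed(42)
  m <- matrix(rnorm(20 * 100), 20, 100)
  s <- compute_svd(m)
  expect_equal(s$u %*% diag(s$d) %*% t(s$v), m, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(s$u) - diag(20))), 1e-10)
  expect_true(all(diff(s$d) <= 1e-12))
  # Eckart-Young: squared Frobenius error of the rank-k truncation equals the
  # sum of the discarded squared singular values
  fro2 <- sum(m^2)
  for (k in c(1, 5, 12)) {
    mk <- s$u[, 1:k] %*% diag(s$d[1:k], k) %*% t(s$v[, 1:k])
    lhs <- sum((m - mk)^2)
    rhs <- sum(s$d[-(1:k)]^2)
    expect_lt(abs(lhs - rhs) / fro2, 1e-10)
  }
})

test_that("SVD sign convention and tall-matrix orientation are consistent", {
  set.seed(3)
  m <- matrix(rnorm(50 * 8), 50, 8)   # tall: Gram on the column side
  s <- compute_svd(m)
  expect_equal(s$u %*% diag(s$d[1:8], 8) %*% t(s$v), m, tolerance = 1e-9)
  for (j in 1:8) expect_gt(s$u[which.max(abs(s$u[, j])), j], 0)
  s2 <- compute_svd(t(m))
  expect_equal(sort(s$d[1:8]), sort(s2$d[1:8]), tolerance = 1e-9)
})

test_that("basis truncation keeps the requested 1-based component range", {
  set.seed(7)
  s <- compute_svd(matrix(rnorm(30 * 200), 30, 200), with_v = FALSE)
  b <- truncate_basis(s)  # default components 2-10
  expect_equal(ncol(b$U_k), 9)
  expect_equal(unname(b$range), c(2L, 10L))
  expect_lt(max(abs(crossprod(b$U_k) - diag(9))), 1e-10)
  full <- truncate_basis(s, first = 1, last = 30)
  expect_equal(full$U_k, s$u)
  expect_error(truncate_basis(s, first = 5, last = 2), "range error")
  expect_error(truncate_basis(s, first = 1, last = 31), "range error")
})

test_that("component 1 of a simulated AP ensemble is the near-constant offset pattern", {
  ens <- assemble_ensemble(small_basis_beats())
  s <- compute_svd(ens, with_v = FALSE)
  u1 <- abs(s$u[, 1])
  expect_lt(sd(u1) / mean(u1), 0.1)  # coefficient of variation
  # and every in-ensemble beat is captured by the full basis
  k <- sum(s$d > 1e-8 * s$d[1])
  beat <- small_basis_beats()[[3]]$phi_H
  proj <- s$u[, 1:k] %*% crossprod(s$u[, 1:k], beat)
  expect_gt(sum(proj^2) / sum(beat^2), 0.99)
})

test_that("incremental Gram accumulation reproduces the ensemble SVD", {
  beats <- small_basis_beats()[1:4]
  g <- NULL
  for (b in beats) g <- ecgi:::gram_accumulate(g, b$phi_H)
  ref <- compute_svd(assemble_ensemble(beats), with_v = FALSE)
  bg <- ecgi:::basis_from_gram(g, 2, 8)
  bt <- truncate_basis(ref, first = 2, last = 8)
  expect_equal(abs(bg$U_k), abs(bt$U_k), tolerance = 1e-6)
  expect_equal(bg$d, bt$d, tolerance = 1e-8)
})
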