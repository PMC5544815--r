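test_that("regularization operators have the stated structure", {
  m <- icosphere(2, 10)
  n <- nrow(m$vertices)
  r0 <- build_regularization_operator(order = 0, n = n)
  expect_equal(as.matrix(r0$R), diag(n))
  ones <- rep(1, n)
  for (ord in 1:2) {
    rop <- build_regularization_operator(m, ord)
    expect_lt(max(abs(as.vector(rop$R %*% ones))), 1e-10)
  }
  r2 <- as.matrix(build_regularization_operator(m, 2)$R)
  expect_equal(r2, t(r2))
  expect_lt(max(abs(rowSums(r2))), 1e-10)
})

test_that("Tikhonov solver matches closed-form cases and limits", {
  expect_equal(tikhonov_solve(diag(2), c(1, 0), lambda = 0), c(1, 0))
  expect_equal(tikhonov_solve(diag(c(1, 2)), c(1, 2), lambda = 1), c(0.5, 0.8))
  x <- tikhonov_solve(diag(c(1, 2)), c(1, 2), lambda = 1e12)
  expect_lt(sqrt(sum(x^2)), 1e-9 * sqrt(5))
  expect_error(tikhonov_solve(matrix(c(1, 1, 1, 1), 2), c(1, 0), lambda = 0),
               "singularity error")
})

test_that("Tikhonov solution equals an independent numeric minimizer on random instances", {
  set.seed(10)
  for (i in 1:20) {
    m <- sample(4:8, 1); n <- sample(3:6, 1)
    A <- matrix(rnorm(m * n), m)
    b <- rnorm(m)
    lam <- 10^runif(1, -3, 1)
    x_pkg <- tikhonov_solve(A, b, lambda = lam)
    # steepest descent on 0.5 x'Hx - g'x with H = 2(A'A + lam I), g = 2 A'b
    x_ref <- bf_quadratic_min(crossprod(A) + lam * diag(n), drop(crossprod(A, b)))
    expect_lt(sqrt(sum((x_pkg - x_ref)^2)) / max(sqrt(sum(x_ref^2)), 1e-12), 1e-6)
  }
})

test_that("L-curve selection returns a grid element, is order-invariant, and is not far off optimal", {
  set.seed(4)
  A <- matrix(rnorm(30 * 10), 30)
  x_true <- rnorm(10)
  b <- drop(A %*% x_true)  # noiseless consistent, well-conditioned
  grid <- 10^seq(-8, 2, length.out = 24)
  lam <- lcurve_select_lambda(A, b, lambda_grid = grid)
  expect_true(lam %in% grid)
  lam2 <- lcurve_select_lambda(A, b, lambda_grid = sample(grid))
  expect_identical(lam, lam2)
  errs <- sapply(grid, function(l) sum((tikhonov_solve(A, b, lambda = l) - x_true)^2))
  err_sel <- errs[which(grid == lam)]
  expect_lt(sqrt(err_sel), 3 * sqrt(min(errs)) + 1e-12)
  expect_error(lcurve_select_lambda(A, b, lambda_grid = grid[1:5]), "at least 10")
})

test_that("budget-constrained lasso solves the textbook cases", {
  expect_equal(pbr_solve(diag(2), diag(2), c(0.3, 0.1), lambda = 0), c(0, 0))
  # constraint inactive: least-squares solution returned
  expect_equal(pbr_solve(diag(2), diag(2), c(0.3, 0.1), lambda = 1),
               c(0.3, 0.1), tolerance = 1e-12)
  # symmetric tied design: equal split of the budget
  X <- rbind(c(1, 1), c(1, -1))
  expect_equal(pbr_solve(X, diag(2), c(1, 0), lambda = 0.5), c(0.25, 0.25),
               tolerance = 1e-10)
})

test_that("lasso path solution matches the projected-gradient oracle on random instances", {
  set.seed(77)
  for (i in 1:20) {
    m <- sample(8:16, 1); k <- sample(3:6, 1)
    X <- matrix(rnorm(m * k), m)
    y <- rnorm(m)
    ols <- qr.solve(X, y)
    budget <- runif(1, 0.05, 1.2) * sum(abs(ols))
    b_pkg <- pbr_solve(X, diag(k), y, lambda = budget)
    b_ref <- bf_lasso(X, y, budget)
    expect_lt(max(abs(b_pkg - b_ref)), 1e-4)
    expect_lte(sum(abs(b_pkg)), budget + 1e-8)
  }
})

test_that("lasso residual decreases and support grows with the budget", {
  set.seed(15)
  X <- matrix(rnorm(20 * 6), 20)
  y <- rnorm(20)
  budgets <- seq(0, 2, length.out = 15)
  res <- sapply(budgets, function(t) {
    b <- pbr_solve(X, diag(6), y, lambda = t)
    c(sqrt(sum((X %*% b - y)^2)), sum(abs(b) > 1e-12))
  })
  expect_true(all(diff(res[1, ]) <= 1e-10))   # residual non-increasing
  expect_true(all(diff(res[2, ]) >= -1e-12))  # nonzero fraction non-decreasing
})

test_that("Tikhonov seminorm is non-increasing in lambda", {
  set.seed(8)
  A <- matrix(rnorm(12 * 9), 12)
  b <- rnorm(12)
  lams <- 10^seq(-6, 3, length.out = 20)
  semin <- sapply(lams, function(l) sqrt(sum(tikhonov_solve(A, b, lambda = l)^2)))
  expect_true(all(diff(semin) <= 1e-10))
})

test_that("cross-validated budget recovers a noiseless in-span signal", {
  set.seed(30)
  X <- matrix(rnorm(40 * 5), 40)
  beta_star <- c(1.5, 0, -0.8, 0, 0.4)
  y <- drop(X %*% beta_star)
  lam <- select_lasso_lambda(X, diag(5), y, folds = 5, seed = 2)
  expect_gte(lam, 0.9 * sum(abs(beta_star)))
  b <- pbr_solve(X, diag(5), y, lambda = lam)
  expect_lt(sqrt(sum((X %*% b - y)^2)) / sqrt(sum(y^2)), 1e-6)
  expect_identical(lam, select_lasso_lambda(X, diag(5), y, folds = 5, seed = 2))
  expect_error(select_lasso_lambda(X, diag(5), y, folds = 1), "folds")
})

test_that("series reconstruction treats instants independently", {
  tm <- small_tm()
  bas <- small_basis()
  set.seed(9)
  beta <- matrix(rnorm(9 * 6), 9)
  phi <- bas$U_k %*% beta
  bp <- forward_project(tm, phi)
  fit <- ecgi_reconstruct(bp, tm, "pbr", basis = bas, seed = 1)
  perm <- c(4, 2, 6, 1, 3, 5)
  bp_perm <- forward_project(tm, phi[, perm])
  fit_perm <- ecgi_reconstruct(bp_perm, tm, "pbr", basis = bas, seed = 1)
  expect_equal(fit_perm$phi_H_hat, fit$phi_H_hat[, perm], tolerance = 1e-9)
  # single-instant input matches the direct per-instant call
  lam1 <- fit$lambda_t[1]
  direct <- pbr_solve(tm, bas, sweep(bp$phi_B, 2, colMeans(bp$phi_B))[, 1], lam1)
  expect_equal(fit$beta_t[, 1], direct, tolerance = 1e-9)
})

test_that("noiseless in-span potentials are recovered almost exactly by PBR", {
  tm <- small_tm()
  bas <- small_basis()
  set.seed(12)
  beta <- matrix(rnorm(9 * 8), 9)
  phi <- bas$U_k %*% beta
  bp <- forward_project(tm, phi)  # noiseless
  fit <- ecgi_reconstruct(bp, tm, "pbr", basis = bas, rereference = FALSE, seed = 1)
  relerr <- sqrt(sum((fit$phi_H_hat - phi)^2) / sum(phi^2))
  expect_lt(relerr, 1e-3)
})

test_that("the fitted-model object supports the standard S3 generics", {
  tm <- small_tm()
  bas <- small_basis()
  set.seed(2)
  phi <- bas$U_k %*% matrix(rnorm(9 * 5), 9)
  bp <- forward_project(tm, phi, snr_db = 40, seed = 1)
  for (fit in list(ecgi_reconstruct(bp, tm, "tikhonov"),
                   ecgi_reconstruct(bp, tm, "pbr", basis = bas, seed = 1))) {
    expect_output(print(fit), "ECGI reconstruction")
    expect_output(print(summary(fit)), "summary")
    expect_equal(dim(fitted(fit)), dim(phi))
    expect_equal(dim(predict(fit, tm)), dim(bp$phi_B))
    r <- residuals(fit, tm)
    expect_equal(dim(r), dim(bp$phi_B))
    expect_length(residuals(fit), ncol(phi))
    grDevices::pdf(NULL)
    plot(fit)
    grDevices::dev.off()
  }
  cf <- coef(ecgi_reconstruct(bp, tm, "pbr", basis = bas, seed = 1))
  expect_equal(dim(cf), c(9, 5))
})
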