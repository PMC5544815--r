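#' Regularization operators on a heart mesh
#'
#' Builds the operator `R` of the penalized least-squares inverse problem:
#' order 0 is the identity (amplitude constraint), order 1 the edge-difference
#' gradient operator scaled by inverse edge length, order 2 the umbrella graph
#' Laplacian. Orders 1 and 2 annihilate spatially constant potentials.
#'
#' @param mesh a [tri_mesh()] (may be `NULL` for order 0 when `n` is given).
#' @param order 0, 1 or 2.
#' @param n number of heart nodes (required if `mesh` is `NULL`).
#' @return Object of class `reg_operator`: list with sparse `R` and `order`.
#' @export
build_regularization_operator <- function(mesh = NULL, order = 0L, n = NULL) {
  order <- as.integer(order)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  if (order == 0L) {
    if (is.null(n)) {
      if (is.null(mesh)) stop("supply mesh or n")
      n <- nrow(mesh$vertices)
    }
    return(structure(list(R = Matrix::Diagonal(n), order = 0L), class = "reg_operator"))
  }
  if (is.null(mesh)) stop("orders 1 and 2 require a mesh")
  e <- mesh_edges(mesh)
  len <- attr(e, "lengths")
  n <- nrow(mesh$vertices)
  if (order == 1L) {
    ne <- nrow(e)
    R <- Matrix::sparseMatrix(i = c(seq_len(ne), seq_len(ne)),
                              j = c(e[, 1], e[, 2]),
                              x = c(1 / len, -1 / len), dims = c(ne, n))
  } else {
    W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = rep(1, 2 * nrow(e)), dims = c(n, n))
    R <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  }
  comp <- graph_components(e, n)
  if (comp > 1L) warning("mesh has ", comp, " connected components")
  structure(list(R = R, order = order), class = "reg_operator")
}

graph_components <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

reg_matrix <- function(R_op, n) {
  if (is.null(R_op)) return(Matrix::Diagonal(n))
  if (inherits(R_op, "reg_operator")) R_op$R else R_op
}

#' Tikhonov-regularized inverse solution at one time instant
#'
#' Returns the unique minimizer of
#' `||A phi - b||^2 + lambda ||R phi||^2`, i.e.
#' `(A'A + lambda R'R)^(-1) A' b`. The weight multiplies the squared seminorm
#' directly (not squared itself).
#'
#' @param A transfer matrix ([compute_transfer_matrix()] result or matrix).
#' @param phi_b body-surface potentials at one instant (length n_electrodes).
#' @param R_op a [build_regularization_operator()] result (`NULL` = identity).
#' @param lambda regularization weight, >= 0.
#' @return numeric vector of heart-node potentials (mV).
#' @export
tikhonov_solve <- function(A, phi_b, R_op = NULL, lambda) {
  Am <- if (inherits(A, "transfer_matrix")) A$A else as.matrix(A)
  if (lambda < 0) stop("lambda must be >= 0")
  R <- reg_matrix(R_op, ncol(Am))
  M <- crossprod(Am) + lambda * as.matrix(Matrix::crossprod(R))
  rhs <- crossprod(Am, phi_b)
  out <- tryCatch(solve(M, rhs), error = function(e)
    stop("singularity error: normal equations not invertible (lambda = ", lambda, ")"))
  drop(out)
}

#' L-curve selection of the Tikhonov weight
#'
#' Sweeps a grid of weights, plots (internally) the log residual norm against
#' the log solution seminorm, and returns the grid element at the point of
#' maximum curvature (the L-curve corner). A flat curve falls back to the
#' smallest grid value with a warning.
#'
#' @inheritParams tikhonov_solve
#' @param lambda_grid positive weights (>= 10 values); default 40 log-spaced
#'   values spanning `[1e-8, 1e2] * sigma1(A)^2`.
#' @return the selected weight (an element of the grid).
#' @export
lcurve_select_lambda <- function(A, phi_b, R_op = NULL, lambda_grid = NULL) {
  Am <- if (inherits(A, "transfer_matrix")) A$A else as.matrix(A)
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(Am)
  if (length(lambda_grid) < 10) stop("lambda grid must have at least 10 values")
  lambda_grid <- sort(lambda_grid)
  R <- reg_matrix(R_op, ncol(Am))
  rho <- eta <- numeric(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    x <- tikhonov_solve(Am, phi_b, R_op, lambda_grid[i])
    rho[i] <- sqrt(sum((Am %*% x - phi_b)^2))
    eta[i] <- sqrt(sum(as.vector(R %*% x)^2))
  }
  pick_lcurve_corner(lambda_grid, rho, eta)
}

default_lambda_grid <- function(Am, n = 40L) {
  s1 <- svd(Am, nu = 0, nv = 0)$d[1]
  exp(seq(log(1e-8 * s1^2), log(1e2 * s1^2), length.out = n))
}

# discrete curvature corner of the (log rho, log eta) curve
pick_lcurve_corner <- function(lambda_grid, rho, eta) {
  scale_r <- max(rho, 1e-300)
  x <- log(pmax(rho, 1e-15 * scale_r))
  y <- log(pmax(eta, 1e-15 * max(eta, 1e-300)))
  t <- log(lambda_grid)
  m <- length(t)
  kap <- rep(NA_real_, m)
  for (i in 2:(m - 1)) {
    h1 <- t[i] - t[i - 1]; h2 <- t[i + 1] - t[i]
    d1x <- (x[i + 1] - x[i - 1]) / (h1 + h2)
    d1y <- (y[i + 1] - y[i - 1]) / (h1 + h2)
    d2x <- 2 * (x[i - 1] / (h1 * (h1 + h2)) - x[i] / (h1 * h2) + x[i + 1] / (h2 * (h1 + h2)))
    d2y <- 2 * (y[i - 1] / (h1 * (h1 + h2)) - y[i] / (h1 * h2) + y[i + 1] / (h2 * (h1 + h2)))
    den <- (d1x^2 + d1y^2)^1.5
    kap[i] <- if (den > 0) (d1x * d2y - d1y * d2x) / den else 0
  }
  if (all(!is.finite(kap) | abs(kap) < 1e-10, na.rm = TRUE)) {
    warning("flat L-curve; falling back to smallest lambda")
    return(lambda_grid[1])
  }
  lambda_grid[which.max(replace(kap, !is.finite(kap), -Inf))]
}

# ---- Lasso path (LARS homotopy with the lasso modification) -----------------
# Returns the knots of the solution path of
#   min ||X b - y||^2  s.t. ||b||_1 <= t
# as t grows from 0. Within a knot segment the solution is linear in t, so a
# budget query interpolates exactly.
lars_lasso_path <- function(X, y, max_steps = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(max_steps)) max_steps <- 8L * p + 20L
  XtX <- crossprod(X)
  beta <- numeric(p)
  cvec <- drop(crossprod(X, y))
  lam <- max(abs(cvec))
  knots_beta <- list(beta)
  knots_l1 <- 0
  knots_lam <- lam
  tol <- 1e-12 * max(lam, 1)
  if (lam <= tol)
    return(list(beta = do.call(rbind, knots_beta), l1 = knots_l1, lam = knots_lam))
  active <- which(abs(cvec) >= lam - max(1e-9 * lam, tol))
  for (step in seq_len(max_steps)) {
    s <- sign(cvec[active])
    dA <- tryCatch(solve(XtX[active, active, drop = FALSE], s),
                   error = function(e) NULL)
    if (is.null(dA)) break
    a <- drop(XtX[, active, drop = FALSE] %*% dA)
    gmax <- lam  # reaching lam = 0 means the least-squares end of the path
    # joining events
    gj <- Inf; jvar <- 0L
    inactive <- setdiff(seq_len(p), active)
    if (length(inactive)) {
      g1 <- (lam - cvec[inactive]) / (1 - a[inactive])
      g2 <- (lam + cvec[inactive]) / (1 + a[inactive])
      cand <- c(g1, g2)
      vars <- c(inactive, inactive)
      ok <- is.finite(cand) & cand > 1e-10 * lam
      if (any(ok) && min(cand[ok]) < gj) {
        gj <- min(cand[ok])
        jvar <- vars[ok][which.min(cand[ok])]
      }
    }
    # sign-crossing events (lasso modification)
    gz <- Inf; zvar <- 0L
    nz <- which(abs(dA) > 0)
    if (length(nz)) {
      g0 <- -beta[active][nz] / dA[nz]
      ok <- is.finite(g0) & g0 > 1e-10 * lam
      if (any(ok)) {
        gz <- min(g0[ok])
        zvar <- active[nz][ok][which.min(g0[ok])]
      }
    }
    gamma <- min(gmax, gj, gz)
    beta[active] <- beta[active] + gamma * dA
    lam <- lam - gamma
    if (gamma == gz) beta[zvar] <- 0
    cvec <- drop(crossprod(X, y - X %*% beta))
    knots_beta[[length(knots_beta) + 1L]] <- beta
    knots_l1 <- c(knots_l1, sum(abs(beta)))
    knots_lam <- c(knots_lam, lam)
    if (lam <= tol) break
    if (gamma == gz) {
      active <- setdiff(active, zvar)
      if (length(active) == 0L) break
    } else if (is.finite(gj) && gamma == gj) {
      active <- sort(c(active, jvar))
    } else {
      break  # gamma == gmax: reached the unconstrained end
    }
  }
  list(beta = do.call(rbind, knots_beta), l1 = knots_l1, lam = knots_lam)
}

lars_query_budget <- function(path, budget) {
  l1 <- path$l1
  if (budget <= 0) return(path$beta[1, ] * 0)
  k <- length(l1)
  if (budget >= l1[k]) return(path$beta[k, ])
  i <- findInterval(budget, l1)  # l1[i] <= budget < l1[i+1]
  f <- (budget - l1[i]) / (l1[i + 1] - l1[i])
  path$beta[i, ] + f * (path$beta[i + 1, ] - path$beta[i, ])
}

#' Sparse (PBR) inverse solution at one time instant
#'
#' Solves the L1-budget-constrained least-squares problem
#' `min ||A U_k beta - phi_b||^2  subject to  ||beta||_1 <= lambda`
#' by the LARS homotopy (the solution path is piecewise linear in the budget,
#' so the constrained solution is obtained exactly). A smaller budget means
#' stronger regularization; `lambda = 0` returns the zero solution.
#'
#' @param A transfer matrix (object or matrix).
#' @param basis a [truncate_basis()] result, or the `U_k` matrix.
#' @param phi_b body-surface potentials at one instant.
#' @param lambda L1 budget, >= 0.
#' @return numeric coefficient vector `beta` (length k); the epicardial
#'   reconstruction is `U_k %*% beta`.
#' @export
pbr_solve <- function(A, basis, phi_b, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  Am <- if (inherits(A, "transfer_matrix")) A$A else as.matrix(A)
  Uk <- if (inherits(basis, "spatial_basis")) basis$U_k else as.matrix(basis)
  X <- Am %*% Uk
  path <- lars_lasso_path(X, phi_b)
  drop(lars_query_budget(path, lambda))
}

#' Cross-validated selection of the Lasso budget
#'
#' Chooses the L1 budget minimizing the mean held-out squared error of a
#' K-fold cross-validation across electrodes (rows of `A U_k`), emulating
#' mean-squared-error-optimal selection of the per-instant regularization
#' parameter. Budgets are evaluated on a log grid scaled to the
#' least-squares solution's L1 norm.
#'
#' @inheritParams pbr_solve
#' @param folds number of folds (2 <= folds <= n_electrodes).
#' @param seed integer seed for the fold assignment.
#' @param budget_grid optional vector of budgets to search.
#' @return the selected budget.
#' @export
select_lasso_lambda <- function(A, basis, phi_b, folds = 5L, seed = 1L,
                                budget_grid = NULL) {
  Am <- if (inherits(A, "transfer_matrix")) A$A else as.matrix(A)
  Uk <- if (inherits(basis, "spatial_basis")) basis$U_k else as.matrix(basis)
  X <- Am %*% Uk
  sel <- cv_budget(X, phi_b, folds = folds, seed = seed, budget_grid = budget_grid)
  sel$budget
}

cv_budget_grid <- function(X, y, n_grid = 40L) {
  path <- lars_lasso_path(X, y)
  t_max <- max(path$l1)
  if (t_max <= 0) return(list(grid = 0, path = path))
  list(grid = c(0, t_max * exp(seq(log(1e-3), log(1.0), length.out = n_grid - 1L))),
       path = path)
}

cv_budget <- function(X, y, folds = 5L, seed = 1L, budget_grid = NULL,
                      fold_id = NULL) {
  m <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2L) stop("configuration error: folds must be >= 2")
  if (folds > m) stop("configuration error: more folds than electrodes")
  gp <- cv_budget_grid(X, y)
  full_path <- gp$path
  grid <- budget_grid %||% gp$grid
  if (length(grid) == 1L)
    return(list(budget = grid[1], path = full_path))
  if (is.null(fold_id))
    fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = m)))
  err <- numeric(length(grid))
  for (f in seq_len(folds)) {
    te <- fold_id == f
    path <- lars_lasso_path(X[!te, , drop = FALSE], y[!te])
    for (g in seq_along(grid)) {
      b <- lars_query_budget(path, grid[g])
      err[g] <- err[g] + sum((X[te, , drop = FALSE] %*% b - y[te])^2)
    }
  }
  list(budget = grid[which.min(err)], path = full_path, cv_error = err / m,
       grid = grid)
}

# ---- series reconstruction (the model-fitting front end) ---------------------

#' Reconstruct epicardial potentials from body-surface potentials
#'
#' The central fitting function of the package. Solves the inverse problem of
#' electrocardiography independently at every time instant, by either
#' classical Tikhonov regularization (order 0/1/2 operator, per-instant
#' L-curve weight) or physiology-based regularization (PBR: Lasso on a
#' truncated SVD basis of simulated action-potential patterns, per-instant
#' cross-validated L1 budget).
#'
#' Body potentials are re-referenced to zero mean across electrodes at every
#' instant before inversion (the spatially constant component of the heart
#' potential is unobservable up to that reference; disable with
#' `rereference = FALSE`).
#'
#' @param phi_B body-surface potentials: a [forward_project()] result or an
#'   n_electrodes x n_timesteps matrix (mV).
#' @param A transfer matrix (object or matrix).
#' @param method `"tikhonov"` or `"pbr"`.
#' @param basis a [truncate_basis()] spatial basis (required for PBR).
#' @param R_op regularization operator for Tikhonov (`NULL` = order 0).
#' @param lambda `NULL` for automatic per-instant selection (L-curve for
#'   Tikhonov, electrode-wise cross-validation for PBR), or a scalar/
#'   per-instant vector of weights (Tikhonov) / L1 budgets (PBR).
#' @param lambda_grid optional grid for the L-curve search.
#' @param folds,seed cross-validation settings for PBR.
#' @param rereference re-reference electrodes to zero mean per instant.
#' @param dt sample interval (ms) when `phi_B` is a plain matrix.
#' @return Object of class `ecgi_recon` with elements `phi_H_hat` (n_nodes x
#'   n_timesteps, mV), `lambda_t`, `residual_t`, and for Tikhonov
#'   `seminorm_t`, for PBR `beta_t` (k x T) and `nonzero_t`. Supports
#'   `print`, `summary`, `coef`, `fitted`, `predict`, `residuals`, `plot`.
#' @export
ecgi_reconstruct <- function(phi_B, A, method = c("tikhonov", "pbr"),
                             basis = NULL, R_op = NULL, lambda = NULL,
                             lambda_grid = NULL, folds = 5L, seed = 1L,
                             rereference = TRUE, dt = NULL) {
  method <- match.arg(method)
  if (inherits(phi_B, "body_potentials")) {
    B <- phi_B$phi_B
    dt <- dt %||% phi_B$dt
  } else {
    B <- as.matrix(phi_B)
    dt <- dt %||% 1
  }
  Am <- if (inherits(A, "transfer_matrix")) A$A else as.matrix(A)
  if (nrow(B) != nrow(Am)) stop("shape error: phi_B rows must match electrodes")
  if (rereference) B <- sweep(B, 2L, colMeans(B))
  nt <- ncol(B)
  if (!is.null(lambda) && length(lambda) == 1L) lambda <- rep(lambda, nt)

  fit <- if (method == "tikhonov") {
    tikhonov_series(Am, B, R_op, lambda, lambda_grid)
  } else {
    if (is.null(basis)) stop("PBR requires a spatial basis")
    pbr_series(Am, basis, B, lambda, folds, seed)
  }
  structure(c(fit,
              list(method = method, dt = dt, n_electrodes = nrow(Am),
                   rereferenced = rereference, phi_B = B, call = match.call())),
            class = "ecgi_recon")
}

tikhonov_series <- function(Am, B, R_op, lambda, lambda_grid) {
  order0 <- is.null(R_op) || (inherits(R_op, "reg_operator") && R_op$order == 0L)
  nt <- ncol(B)
  if (order0) {
    sv <- svd(Am)
    d <- sv$d
    ub <- crossprod(sv$u, B)             # r x T
    perp <- pmax(colSums(B^2) - colSums(ub^2), 0)
    if (is.null(lambda)) {
      grid <- lambda_grid %||% (exp(seq(log(1e-8), log(1e2), length.out = 40L)) * d[1]^2)
      grid <- sort(grid)
      ng <- length(grid)
      rho <- eta <- matrix(0, ng, nt)
      for (g in seq_len(ng)) {
        fl <- d / (d^2 + grid[g])
        rl <- grid[g] / (d^2 + grid[g])
        eta[g, ] <- sqrt(colSums((fl * ub)^2))
        rho[g, ] <- sqrt(colSums((rl * ub)^2) + perp)
      }
      lambda <- vapply(seq_len(nt), function(t)
        pick_lcurve_corner(grid, rho[, t], eta[, t]), numeric(1))
    }
    coef <- ub * (d / outer(d^2, lambda, "+"))
    phi <- sv$v %*% coef
    resid <- sqrt(colSums((Am %*% phi - B)^2))
    semin <- sqrt(colSums(phi^2))
  } else {
    phi <- matrix(0, ncol(Am), nt)
    auto <- is.null(lambda)
    if (auto) {
      lambda <- numeric(nt)
      grid <- lambda_grid %||% default_lambda_grid(Am)
    }
    for (t in seq_len(nt)) {
      if (auto) lambda[t] <- lcurve_select_lambda(Am, B[, t], R_op, grid)
      phi[, t] <- tikhonov_solve(Am, B[, t], R_op, lambda[t])
    }
    R <- reg_matrix(R_op, ncol(Am))
    resid <- sqrt(colSums((Am %*% phi - B)^2))
    semin <- sqrt(colSums(as.matrix(R %*% phi)^2))
  }
  list(phi_H_hat = phi, lambda_t = lambda, residual_t = resid, seminorm_t = semin)
}

pbr_series <- function(Am, basis, B, lambda, folds, seed) {
  Uk <- if (inherits(basis, "spatial_basis")) basis$U_k else as.matrix(basis)
  X <- Am %*% Uk
  nt <- ncol(B)
  k <- ncol(Uk)
  beta <- matrix(0, k, nt)
  lam_out <- numeric(nt)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = nrow(X))))
  for (t in seq_len(nt)) {
    y <- B[, t]
    if (is.null(lambda)) {
      sel <- cv_budget(X, y, folds = folds, fold_id = fold_id)
      lam_out[t] <- sel$budget
      beta[, t] <- lars_query_budget(sel$path, sel$budget)
    } else {
      lam_out[t] <- lambda[t]
      beta[, t] <- pbr_solve_x(X, y, lambda[t])
    }
  }
  phi <- Uk %*% beta
  list(phi_H_hat = phi, lambda_t = lam_out, beta_t = beta,
       residual_t = sqrt(colSums((X %*% beta - B)^2)),
       nonzero_t = colSums(abs(beta) > 1e-12))
}

pbr_solve_x <- function(X, y, budget) {
  drop(lars_query_budget(lars_lasso_path(X, y), budget))
}

#' @export
print.ecgi_recon <- function(x, ...) {
  cat(sprintf("ECGI reconstruction (%s): %d heart nodes x %d instants (dt = %g ms)\n",
              x$method, nrow(x$phi_H_hat), ncol(x$phi_H_hat), x$dt))
  cat(sprintf("  per-instant lambda: median %.3g [%.3g, %.3g]\n",
              stats::median(x$lambda_t), min(x$lambda_t), max(x$lambda_t)))
  if (!is.null(x$nonzero_t))
    cat(sprintf("  nonzero coefficients per instant: median %g of %d\n",
                stats::median(x$nonzero_t), nrow(x$beta_t)))
  invisible(x)
}

#' @export
summary.ecgi_recon <- function(object, ...) {
  out <- list(method = object$method,
              n_nodes = nrow(object$phi_H_hat), n_t = ncol(object$phi_H_hat),
              dt = object$dt,
              lambda = summary(object$lambda_t),
              residual = summary(object$residual_t),
              nonzero = if (!is.null(object$nonzero_t)) summary(object$nonzero_t))
  class(out) <- "summary.ecgi_recon"
  out
}

#' @export
print.summary.ecgi_recon <- function(x, ...) {
  cat(sprintf("ECGI reconstruction summary (%s)\n", x$method))
  cat(sprintf("  %d heart nodes, %d instants, dt = %g ms\n", x$n_nodes, x$n_t, x$dt))
  cat("  lambda(t):\n"); print(x$lambda)
  cat("  residual norm per instant:\n"); print(x$residual)
  if (!is.null(x$nonzero)) { cat("  nonzero coefficients:\n"); print(x$nonzero) }
  invisible(x)
}

#' @export
coef.ecgi_recon <- function(object, ...) {
  if (object$method == "pbr") object$beta_t else object$phi_H_hat
}

#' @export
fitted.ecgi_recon <- function(object, ...) object$phi_H_hat

#' Predicted body-surface potentials of a reconstruction
#'
#' @param object an [ecgi_reconstruct()] fit.
#' @param A transfer matrix used for the forward map.
#' @param ... unused.
#' @return matrix of predicted electrode potentials.
#' @export
predict.ecgi_recon <- function(object, A, ...) {
  Am <- if (inherits(A, "transfer_matrix")) A$A else as.matrix(A)
  Am %*% object$phi_H_hat
}

#' @export
residuals.ecgi_recon <- function(object, A = NULL, ...) {
  if (is.null(A)) return(object$residual_t)
  object$phi_B - predict(object, A)
}

#' Plot reconstructed electrograms and the regularization trace
#'
#' @param x an [ecgi_reconstruct()] fit.
#' @param nodes heart-node indices to plot (default: 4 spread across nodes).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ecgi_recon <- function(x, nodes = NULL, ...) {
  if (is.null(nodes))
    nodes <- unique(round(seq(1, nrow(x$phi_H_hat), length.out = 4)))
  tt <- (seq_len(ncol(x$phi_H_hat)) - 1) * x$dt
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(tt, t(x$phi_H_hat[nodes, , drop = FALSE]), type = "l",
                    xlab = "time (ms)", ylab = "potential (mV)",
                    main = paste("reconstructed electrograms,", x$method), ...)
  graphics::plot(tt, x$lambda_t, type = "l", log = "y",
                 xlab = "time (ms)", ylab = "lambda(t)")
  invisible(x)
}
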