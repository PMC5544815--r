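test_that("default phantom mirrors the target geometry scale", {
  g <- generate_phantom(seed = 2)
  expect_lt(abs(nrow(g$heart$vertices) - 1700), 50)  # approximately 1700 nodes
  expect_equal(nrow(g$electrodes), 200)
  expect_true(nrow(g$electrodes) >= 184 && nrow(g$electrodes) <= 216)
  validate_tri_mesh(g$heart, require_sphere = TRUE)
  validate_tri_mesh(g$torso, require_sphere = TRUE)
})

test_that("phantom rejects impossible geometry and is deterministic per seed", {
  expect_error(generate_phantom(heart_radius = 50, torso_radius = 40,
                                n_heart_nodes = 42, n_torso_nodes = 92),
               "geometry error")
  a <- generate_phantom(n_heart_nodes = 42, n_torso_nodes = 92,
                        n_electrodes = 16, seed = 9)
  b <- generate_phantom(n_heart_nodes = 42, n_torso_nodes = 92,
                        n_electrodes = 16, seed = 9)
  expect_identical(a$electrodes, b$electrodes)
})

test_that("analytic annulus attenuation has its closed-form values", {
  expect_equal(analytic_spheres_attenuation(0, 1, 2), 1)
  expect_equal(analytic_spheres_attenuation(0, 13, 57), 1)
  expect_equal(analytic_spheres_attenuation(1, 1, 2), 0.6)
  expect_equal(analytic_spheres_attenuation(2, 1, 2), 20 / 67)
  expect_error(analytic_spheres_attenuation(1, 2, 1), "domain error")
  expect_error(analytic_spheres_attenuation(1, 2, 2), "domain error")
})

test_that("transfer matrix maps constants to constants (row sums 1)", {
  tm <- small_tm()
  expect_lt(max(abs(rowSums(tm$A) - 1)), 1e-3)
  c_in <- rep(2.5, ncol(tm$A))
  expect_equal(as.vector(tm$A %*% c_in), rep(2.5, nrow(tm$A)), tolerance = 1e-9)
})

test_that("BEM agrees with the analytic concentric-spheres solution and converges", {
  err_for <- function(fh, ft) {
    geom <- generate_phantom(40, 120, n_heart_nodes = 10 * fh^2 + 2,
                             n_torso_nodes = 10 * ft^2 + 2, n_electrodes = 16,
                             seed = 1)
    tm <- compute_transfer_matrix(geom, electrodes = geom$torso$vertices)
    sapply(1:2, function(l) {
      f_an <- analytic_spheres_attenuation(l, 40, 120)
      zh <- geom$heart$vertices[, 3] / 40
      zt <- geom$torso$vertices[, 3] / 120
      phi_h <- if (l == 1) zh else 0.5 * (3 * zh^2 - 1)
      exact <- f_an * (if (l == 1) zt else 0.5 * (3 * zt^2 - 1))
      got <- as.vector(tm$A %*% phi_h)
      sqrt(sum((got - exact)^2) / sum(exact^2))
    })
  }
  coarse <- err_for(5, 6)
  expect_lt(max(coarse), 0.05)
  fine <- err_for(7, 8)
  expect_true(all(fine <= coarse + 1e-6))  # refinement does not worsen the oracle error
})

test_that("forward projection is exact and linear without noise", {
  tm <- small_tm()
  n <- ncol(tm$A)
  set.seed(5)
  x <- matrix(rnorm(n * 7), n)
  y <- matrix(rnorm(n * 7), n)
  bx <- forward_project(tm, x)$phi_B
  by <- forward_project(tm, y)$phi_B
  bxy <- forward_project(tm, x + y)$phi_B
  expect_equal(bx, tm$A %*% x, tolerance = 1e-14)
  expect_equal(bxy, bx + by, tolerance = 1e-12)
  cc <- forward_project(tm, matrix(4.2, n, 3))$phi_B
  expect_equal(as.vector(cc), rep(4.2, 3 * nrow(tm$A)), tolerance = 1e-9)
  expect_error(forward_project(tm, matrix(0, n + 1, 2)), "shape error")
})

test_that("requested SNR is achieved within 1 dB and noise is seed-deterministic", {
  tm <- small_tm()
  set.seed(11)
  phi <- matrix(rnorm(ncol(tm$A)), ncol(tm$A)) %*% t(sin(seq(0, 6 * pi, length.out = 550)))
  clean <- tm$A %*% phi
  for (snr in c(20, 30)) {
    bp <- forward_project(tm, phi, snr_db = snr, seed = 3)
    noise <- bp$phi_B - clean
    measured <- 10 * log10(mean(clean^2) / mean(noise^2))
    expect_lt(abs(measured - snr), 1)
    bp2 <- forward_project(tm, phi, snr_db = snr, seed = 3)
    expect_identical(bp$phi_B, bp2$phi_B)
  }
})

test_that("electrode-node matching is exact, tie-broken low, and equals brute force", {
  m <- icosphere(2, 30)
  expect_identical(match_electrodes_to_nodes(m$vertices[7, , drop = FALSE], m), 7L)
  # point equidistant between the two endpoints of an edge -> lowest index wins
  e <- mesh_edges(m)
  ed <- e[which(e[, 1] == 3L)[1], ]
  mid <- (m$vertices[ed[1], ] + m$vertices[ed[2], ]) / 2
  got <- match_electrodes_to_nodes(matrix(mid, 1), m)
  expect_equal(sum((m$vertices[ed[1], ] - mid)^2), sum((m$vertices[ed[2], ] - mid)^2))
  expect_identical(got, 3L)
  set.seed(21)
  pts <- matrix(rnorm(60), ncol = 3) * 20
  expect_equal(match_electrodes_to_nodes(pts, m), bf_nearest(pts, m$vertices))
})
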