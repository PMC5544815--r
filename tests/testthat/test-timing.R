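test_that("window estimation finds QRS onset near the stimulus and honours overrides", {
  w <- small_windows()
  expect_lt(abs(w$qrs[1] - 10), 10)  # stimulus delivered at 10 ms
  expect_lt(w$qrs[2], w$t_wave[1] + 1e-9)
  expect_error(estimate_windows(matrix(0, 5, 100), 1), "windowing error")
  w2 <- estimate_windows(matrix(0, 5, 100), 1, qrs = c(3, 40), t_wave = c(80, 120))
  expect_equal(w2$qrs, c(3, 40))
  expect_equal(w2$t_wave, c(80, 120))
})

test_that("temporal activation marks the steepest downslope (electrogram polarity)", {
  t0 <- 40
  tt <- seq(0, 100, by = 0.5)
  egm <- -tanh((tt - t0) / 2)
  tau <- activation_time_temporal(egm, dt = 0.5, windows = c(0, 100))
  expect_lt(abs(tau - t0), 0.5 + 1e-9)
  # enumerated example: max drop of 1.0 between samples 3 and 4 (t = 2)
  s <- c(1, 1, 0.5, -0.5, -1, -1)
  expect_equal(as.numeric(activation_time_temporal(s, 1, c(0, 5))), 2)
  inc <- activation_time_temporal(sort(rnorm(20)), 1, c(0, 19))
  expect_true(is.na(inc))
  expect_true(attr(inc, "undefined"))
})

test_that("temporal recovery mirrors activation with opposite slope", {
  t1 <- 60
  tt <- seq(0, 120, by = 0.5)
  egm <- tanh((tt - t1) / 2)
  tau <- recovery_time_temporal(egm, 0.5, windows = c(0, 120))
  expect_lt(abs(tau - t1), 0.5 + 1e-9)
  s <- c(1, 1, 0.5, -0.5, -1, -1)
  expect_equal(as.numeric(recovery_time_temporal(-s, 1, c(0, 5))), 2)
  flat <- recovery_time_temporal(rep(1, 10), 1, c(0, 9))
  expect_true(is.na(flat))
})

test_that("AP polarity flips both temporal criteria", {
  tt <- seq(0, 100, by = 1)
  up <- tanh((tt - 30) / 2)   # AP-like upstroke at activation
  tau <- activation_time_temporal(up, 1, c(0, 100), polarity = "ap")
  expect_lt(abs(tau - 30), 1 + 1e-9)
})

test_that("spatiotemporal criterion orders a plane wave by passage time and matches brute force", {
  fg <- flat_grid_mesh(8, 5, h = 2)
  n <- nrow(fg$vertices)
  tt <- seq(0, 60, by = 1)
  speed <- 0.5
  # electrogram-polarity plane wave: downward deflection as the front passes
  phi <- t(sapply(seq_len(n), function(i)
    -tanh((tt - fg$vertices[i, 1] / speed - 10) / 1.5)))
  w <- analysis_windows(c(0, 55), c(56, 60))
  a <- activation_time_spatiotemporal(phi, fg, w, dt = 1)
  passage <- fg$vertices[, 1] / speed + 10
  expect_gt(cor(a$tau, passage, method = "spearman"), 0.99)
  # brute-force evaluation of the product criterion at every instant
  op <- spatial_gradient_operator(fg)
  gm <- gradient_magnitude(op, phi)
  dphi <- (phi[, -1] - phi[, -ncol(phi)]) / 1
  idx <- 1:55
  ref <- sapply(seq_len(n), function(i) {
    prods <- gm[i, idx] * dphi[i, idx]
    idx[which.min(prods)] - 1
  })
  expect_equal(a$tau, ref)
  expect_false(any(a$fallback))
  # time-reversed wave: recovery ordering is the reverse of activation
  phir <- phi[, rev(seq_along(tt))]
  wr <- analysis_windows(c(0, 2), c(3, 60))
  r <- recovery_time_spatiotemporal(phir, fg, wr, dt = 1)
  expect_lt(cor(r$tau, passage, method = "spearman"), -0.99)
})

test_that("spatially uniform records fall back to the temporal criterion with a flag", {
  fg <- flat_grid_mesh(4, 4)
  tt <- seq(0, 50, by = 1)
  uni <- matrix(rep(-tanh((tt - 20) / 2), each = 16), 16)
  w <- analysis_windows(c(0, 45), c(46, 50))
  a <- activation_time_spatiotemporal(uni, fg, w, dt = 1)
  expect_true(all(a$fallback))
  expect_true(all(abs(a$tau - 20) <= 1 + 1e-9))
})

test_that("timing maps of simulated beats are physiological and locate the origin", {
  beat <- small_beat()
  w <- small_windows()
  tmap <- compute_timing_map(beat$phi_H, 1, w, "temporal", polarity = "ap")
  expect_true(all(tmap$tau_rec_ms > tmap$tau_act_ms, na.rm = TRUE))
  # temporal estimates reproduce the simulator's threshold-crossing sequence
  at_sim <- beat_activation_times(beat)
  expect_gt(cor(at_sim, tmap$tau_act_ms, method = "spearman", use = "complete.obs"),
            0.98)
  # earliest-activation localization lands within one edge of the pacing site
  pred <- localize_origin(tmap)
  edge_len <- max(attr(mesh_edges(small_geom()$heart), "lengths"))
  expect_lte(localization_error(pred, beat$origin, small_geom()$heart), edge_len)
  # spatiotemporal and temporal agree closely on the clean simulated beat
  smap <- compute_timing_map(beat$phi_H, 1, w, "spatiotemporal",
                             mesh = small_geom()$heart, polarity = "ap")
  expect_gt(cor(tmap$tau_act_ms, smap$tau_act_ms, use = "complete.obs"), 0.95)
})

test_that("origin localization uses the earliest time with low-index tie-breaking", {
  m <- icosphere(2, 20)
  d <- ecgi:::mesh_graph_distances(m, 5L)
  expect_identical(localize_origin(d), 5L)
  tau <- rep(10, 12); tau[c(3, 9)] <- 1
  expect_identical(localize_origin(tau), 3L)
  expect_error(localize_origin(rep(NA_real_, 5)), "no defined")
})

test_that("localization error is a distance in mm with a geodesic option", {
  m <- icosphere(3, 40)
  expect_equal(localization_error(7, 7, m), 0)
  anti <- match_electrodes_to_nodes(-m$vertices[1, , drop = FALSE], m)
  expect_equal(localization_error(anti, 1, m), 80, tolerance = 1e-9)
  set.seed(6)
  for (i in 1:5) {
    a <- sample(nrow(m$vertices), 1); b <- sample(nrow(m$vertices), 1)
    expect_equal(localization_error(a, b, m),
                 sqrt(sum((m$vertices[a, ] - m$vertices[b, ])^2)))
  }
  expect_gte(localization_error(anti, 1, m, method = "geodesic"),
             localization_error(anti, 1, m))
})
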