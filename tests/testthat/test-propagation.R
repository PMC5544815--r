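test_that("uncoupled nodes reproduce the single-cell solution exactly", {
  m <- icosphere(2, 20)
  model <- fhn()
  pp <- propagation_params(0, n_steps = 300, origin = 5, substeps = 4)
  beat <- simulate_beat(m, model, pp)
  e <- mesh_edges(m)
  ring <- unique(c(5L, e[e[, 1] == 5, 2], e[e[, 2] == 5, 1]))
  # non-stimulated nodes stay flat at the resting voltage
  others <- setdiff(seq_len(nrow(m$vertices)), ring)
  expect_lt(max(abs(beat$phi_H[others, ] + 80)), 1e-9)
  # stimulated nodes equal an isolated cell given the same stimulus
  single <- simulate_beat(list(vertices = matrix(0, 1, 3),
                               edges = matrix(integer(0), 0, 2)),
                          model, propagation_params(0, n_steps = 300,
                                                    origin = 1, substeps = 4))
  for (i in ring)
    expect_equal(beat$phi_H[i, ], single$phi_H[1, ], tolerance = 1e-12)
})

test_that("a stimulated chain activates in order of distance", {
  n <- 20
  mesh <- list(vertices = cbind(seq_len(n) * 5, 0, 0),
               edges = cbind(1:(n - 1), 2:n))
  beat <- simulate_beat(mesh, fhn(),
                        propagation_params(4, dt = 0.5, n_steps = 800, origin = 1))
  at <- beat_activation_times(beat)
  expect_false(anyNA(at))
  # nodes 1 and 2 are co-stimulated (origin + 1-ring); beyond them the wave
  # reaches each node strictly later than its predecessor
  expect_true(all(diff(at[-1]) > 0))
  expect_lte(max(at[1:2]), min(at[-(1:2)]))
})

test_that("all phases occur in order: full activation then full recovery", {
  beat <- small_beat()
  v <- beat$phi_H
  at <- beat_activation_times(beat)
  expect_false(anyNA(at))  # propagating front reaches every node
  all_active <- which(apply(v > -40, 2, all))
  expect_gt(length(all_active), 0)  # fully activated ventricles
  recovered <- which(apply(v < -70, 2, all))  # repolarized everywhere
  recovered <- recovered[recovered > min(all_active)]
  expect_gt(length(recovered), 0)   # fully recovered after full activation
  expect_lt(min(all_active), min(recovered))
})

test_that("activation time grows with graph distance from the origin", {
  beat <- small_beat()
  at <- beat_activation_times(beat)
  d <- ecgi:::mesh_graph_distances(small_geom()$heart, beat$origin)
  expect_gt(cor(at, d, method = "spearman"), 0.95)
})

test_that("antipodal pacing on a symmetric mesh mirrors the activation map", {
  m <- icosphere(3, 20)
  model <- fhn()
  v1 <- 10L
  anti <- match_electrodes_to_nodes(-m$vertices[v1, , drop = FALSE], m)
  expect_lt(sum((m$vertices[anti, ] + m$vertices[v1, ])^2), 1e-16)
  b1 <- simulate_beat(m, model, propagation_params(4, n_steps = 300, origin = v1))
  b2 <- simulate_beat(m, model, propagation_params(4, n_steps = 300, origin = anti))
  mirror <- match_electrodes_to_nodes(-m$vertices, m)
  a1 <- beat_activation_times(b1)
  a2 <- beat_activation_times(b2)
  expect_lt(max(abs(a1 - a2[mirror])), 1 + 1e-12)  # within one sample
})

test_that("gbar calibration hits the target window, is monotone, and validates its bracket", {
  g <- small_gbar()
  expect_equal(attr(calibrate_gbar(small_geom()$heart, fhn(), n_steps = 400),
                    "spread"), attr(calibrate_gbar(small_geom()$heart, fhn(),
                                                   n_steps = 400), "spread"))
  beat <- simulate_beat(small_geom()$heart, fhn(),
                        propagation_params(g, n_steps = 400, origin = 1))
  sp <- diff(range(beat_activation_times(beat)))
  expect_true(sp >= 60 && sp <= 100)
  spreads <- sapply(c(2, 4, 8), function(gb) {
    b <- simulate_beat(small_geom()$heart, fhn(),
                       propagation_params(gb, n_steps = 450, origin = 1))
    diff(range(beat_activation_times(b)))
  })
  expect_true(all(diff(spreads) < 0))  # larger gbar -> smaller spread
  expect_error(calibrate_gbar(small_geom()$heart, fhn(), bracket = c(0, 0)),
               "calibration error")
})

test_that("region labels cover the mesh and are rotation-equivariant", {
  m <- small_geom()$heart
  lab <- label_regions(m)
  expect_false(anyNA(lab))
  expect_true(all(table(lab) > 0))
  expect_equal(sum(lab == "LV") + sum(lab == "RV") + sum(lab == "BASE_APEX"),
               nrow(m$vertices))
  # rigid rotation applied to mesh, axis and longitude reference
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  m2 <- m
  m2$vertices <- m$vertices %*% t(R)
  lab2 <- label_regions(m2, axis = as.vector(R %*% c(0, 0, 1)),
                        ref = as.vector(R %*% c(1, 0, 0)))
  expect_identical(as.character(lab2), as.character(lab))
})

test_that("beat-origin sampling is deterministic, spaced and region-confined", {
  m <- small_geom()$heart
  lab <- label_regions(m)
  o1 <- choose_beat_origins(lab, m, "LV", 10, seed = 3)
  o2 <- choose_beat_origins(lab, m, "LV", 10, seed = 3)
  expect_identical(o1, o2)
  expect_length(unique(o1), 10)
  expect_true(all(lab[o1] == "LV"))
  sp <- 6
  o3 <- choose_beat_origins(lab, m, "RV", 8, min_spacing = sp, seed = 1)
  dmat <- as.matrix(dist(m$vertices[o3, ]))
  expect_true(all(dmat[upper.tri(dmat)] >= sp))
  n_lv <- sum(lab == "LV")
  expect_error(choose_beat_origins(lab, m, "LV", n_lv + 1L, seed = 1),
               "sampling error")
})
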