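test_that("icosphere is a closed, consistently wound sphere mesh", {
  for (f in c(1, 3, 5)) {
    m <- icosphere(f, 40)
    expect_equal(nrow(m$vertices), 10 * f^2 + 2)
    chi <- validate_tri_mesh(m, require_sphere = TRUE)
    expect_identical(chi, 2L + 0L * chi)  # Euler characteristic 2
    expect_equal(unname(sqrt(rowSums(m$vertices^2))), rep(40, nrow(m$vertices)))
  }
  # total face area converges to the sphere area from below
  a1 <- sum(mesh_face_areas(icosphere(4, 1)))
  a2 <- sum(mesh_face_areas(icosphere(8, 1)))
  expect_true(a1 < a2 && a2 < 4 * pi)
  expect_gt(a2 / (4 * pi), 0.99)
})

test_that("mesh validation rejects broken meshes", {
  m <- icosphere(2, 1)
  # flip one face -> inconsistent winding
  bad <- m
  bad$faces[1, ] <- bad$faces[1, c(1, 3, 2)]
  expect_error(validate_tri_mesh(bad), "winding|manifold")
  # remove one face -> boundary
  open <- m
  open$faces <- open$faces[-1, , drop = FALSE]
  expect_error(validate_tri_mesh(open), "not closed")
})

test_that("vertex dual areas partition the surface and normals are radial", {
  m <- icosphere(4, 25)
  va <- mesh_vertex_areas(m)
  expect_equal(sum(va), sum(mesh_face_areas(m)))
  nrm <- mesh_vertex_normals(m)
  radial <- m$vertices / 25
  expect_gt(min(rowSums(nrm * radial)), 0.99)
})

test_that("PLY and OFF round-trip a mesh", {
  m <- icosphere(2, 40)
  for (fmt in c("ply", "off")) {
    path <- tempfile(fileext = paste0(".", fmt))
    if (fmt == "ply") { write_ply(m, path); m2 <- read_ply(path) }
    else { write_off(m, path); m2 <- read_off(path) }
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
    expect_identical(m2$faces, m$faces)
    unlink(path)
  }
})

test_that("surface gradient operator annihilates constants and is exact on linear fields", {
  m <- icosphere(3, 10)
  op <- spatial_gradient_operator(m)
  gm <- gradient_magnitude(op, rep(3.7, nrow(m$vertices)))
  expect_lt(max(abs(gm)), 1e-10)
  # flat grid: u = 2x + 3y has gradient magnitude sqrt(13) everywhere
  fg <- flat_grid_mesh(7, 7)
  opf <- spatial_gradient_operator(fg)
  u <- 2 * fg$vertices[, 1] + 3 * fg$vertices[, 2]
  gmf <- gradient_magnitude(opf, u)
  expect_equal(as.vector(gmf), rep(sqrt(13), nrow(fg$vertices)), tolerance = 1e-10)
})

test_that("graph distances match a brute-force Bellman-Ford relaxation", {
  m <- icosphere(2, 5)
  d <- ecgi:::mesh_graph_distances(m, 1L)
  e <- mesh_edges(m)
  len <- attr(e, "lengths")
  ref <- rep(Inf, nrow(m$vertices)); ref[1] <- 0
  for (rep_i in seq_len(nrow(m$vertices))) {
    for (k in seq_len(nrow(e))) {
      i <- e[k, 1]; j <- e[k, 2]
      ref[j] <- min(ref[j], ref[i] + len[k])
      ref[i] <- min(ref[i], ref[j] + len[k])
    }
  }
  expect_equal(d, ref, tolerance = 1e-12)
})
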