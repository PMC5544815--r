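#' Triangulated surface mesh
#'
#' Construct a triangle surface mesh from a vertex matrix and a face index
#' matrix. Meshes represent closed epicardial or torso surfaces; coordinates
#' are in millimetres and faces are wound consistently so that face normals
#' point outward.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates, mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices per triangle.
#' @param validate if `TRUE` (default) check that the mesh is a closed,
#'   consistently oriented 2-manifold with no degenerate faces.
#' @return An object of class `tri_mesh`: a list with elements `vertices`
#'   and `faces`.
#' @seealso [icosphere()], [validate_tri_mesh()]
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (anyNA(vertices) || any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) stop("face indices out of range")
  mesh <- structure(list(vertices = unname(vertices), faces = unname(faces)),
                    class = "tri_mesh")
  if (validate) validate_tri_mesh(mesh)
  mesh
}

#' Validate a closed triangle mesh
#'
#' Checks that every directed edge appears exactly once and its reverse
#' exactly once (closed, orientable, consistently wound 2-manifold), that no
#' face has zero area, and reports the Euler characteristic.
#'
#' @param mesh a [tri_mesh()].
#' @param require_sphere if `TRUE`, additionally require Euler characteristic 2.
#' @return Invisibly, the Euler characteristic. Errors on violation.
#' @export
validate_tri_mesh <- function(mesh, require_sphere = FALSE) {
  f <- mesh$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key)) stop("mesh error: duplicated directed edge (inconsistent winding or non-manifold)")
  rev_key <- paste(he[, 2], he[, 1])
  if (!all(rev_key %in% key)) stop("mesh error: boundary edge found, mesh is not closed")
  if (any(mesh_face_areas(mesh) <= 1e-12)) stop("mesh error: zero-area face")
  n_e <- nrow(he) / 2
  chi <- nrow(mesh$vertices) - n_e + nrow(f)
  if (require_sphere && chi != 2) stop("mesh error: Euler characteristic ", chi, ", expected 2")
  invisible(chi)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Geodesic icosphere
#'
#' Triangulated sphere obtained by frequency-`freq` subdivision of a regular
#' icosahedron, with vertices projected to the sphere. The result has
#' `10 * freq^2 + 2` vertices, is a closed consistently wound 2-manifold,
#' and inherits the icosahedron's antipodal symmetry.
#'
#' @param freq subdivision frequency (positive integer).
#' @param radius sphere radius, mm.
#' @param center sphere centre (length-3).
#' @param scale per-axis scale factors applied after spherical projection
#'   (ellipsoids; default `c(1, 1, 1)`).
#' @return A [tri_mesh()].
#' @export
icosphere <- function(freq, radius = 1, center = c(0, 0, 0), scale = c(1, 1, 1)) {
  freq <- as.integer(freq)
  if (freq < 1L) stop("freq must be >= 1")
  base <- icosahedron()
  v <- base$vertices
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- vector("list", 10L * freq^2 + 2L)
  nv <- 0L
  tris <- vector("list", 20L * freq^2)
  nt <- 0L
  getv <- function(p) {
    key <- paste(sprintf("%.9f", p), collapse = ",")
    id <- key_env[[key]]
    if (is.null(id)) {
      nv <<- nv + 1L
      verts[[nv]] <<- p
      key_env[[key]] <- nv
      id <- nv
    }
    id
  }
  for (fi in seq_len(nrow(base$faces))) {
    a <- v[base$faces[fi, 1], ]; b <- v[base$faces[fi, 2], ]; c3 <- v[base$faces[fi, 3], ]
    idx <- matrix(NA_integer_, freq + 1L, freq + 1L)
    for (i in 0:freq) for (j in 0:(freq - i))
      idx[i + 1L, j + 1L] <- getv((a * (freq - i - j) + b * i + c3 * j) / freq)
    for (i in 0:(freq - 1L)) for (j in 0:(freq - 1L - i)) {
      nt <- nt + 1L
      tris[[nt]] <- c(idx[i + 1L, j + 1L], idx[i + 2L, j + 1L], idx[i + 1L, j + 2L])
      if (j < freq - 1L - i) {
        nt <- nt + 1L
        tris[[nt]] <- c(idx[i + 2L, j + 1L], idx[i + 2L, j + 2L], idx[i + 1L, j + 2L])
      }
    }
  }
  V <- do.call(rbind, verts[seq_len(nv)])
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2L, scale, "*")
  V <- sweep(V, 2L, center, "+")
  tri_mesh(V, do.call(rbind, tris[seq_len(nt)]), validate = FALSE)
}

# Regular icosahedron with outward-wound faces, circumradius sqrt(1+phi^2).
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  faces <- list()
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    if (abs(sum((v[i, ] - v[j, ])^2) - 4) < 1e-9 &&
        abs(sum((v[j, ] - v[k, ])^2) - 4) < 1e-9 &&
        abs(sum((v[i, ] - v[k, ])^2) - 4) < 1e-9)
      faces[[length(faces) + 1L]] <- c(i, j, k)
  }
  faces <- do.call(rbind, faces)
  for (fi in seq_len(nrow(faces))) {
    tr <- faces[fi, ]
    nrm <- cross3(v[tr[2], ] - v[tr[1], ], v[tr[3], ] - v[tr[1], ])
    if (sum(nrm * colMeans(v[tr, ])) < 0) faces[fi, ] <- tr[c(1L, 3L, 2L)]
  }
  list(vertices = v, faces = faces)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Unnormalized face normals (rows), length = 2 * face area.
mesh_face_normals_raw <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' @rdname mesh_vertex_areas
#' @export
mesh_face_areas <- function(mesh) {
  0.5 * sqrt(rowSums(mesh_face_normals_raw(mesh)^2))
}

#' Vertex dual areas and vertex normals
#'
#' `mesh_vertex_areas` assigns one third of each incident triangle's area to
#' each of its vertices (barycentric dual area). `mesh_vertex_normals` returns
#' the area-weighted average of incident face normals, normalized.
#'
#' @param mesh a [tri_mesh()].
#' @return numeric vector of areas (mm^2), or an n x 3 matrix of unit normals.
#' @export
mesh_vertex_areas <- function(mesh) {
  fa <- mesh_face_areas(mesh)
  n <- nrow(mesh$vertices)
  acc <- rowsum(rep(fa / 3, 3L), group = c(mesh$faces), reorder = TRUE)
  out <- numeric(n)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' @rdname mesh_vertex_areas
#' @export
mesh_vertex_normals <- function(mesh) {
  fn <- mesh_face_normals_raw(mesh)  # length 2A, area weighting for free
  n <- nrow(mesh$vertices)
  out <- matrix(0, n, 3L)
  for (k in 1:3) {
    acc <- rowsum(fn, group = mesh$faces[, k], reorder = TRUE)
    out[as.integer(rownames(acc)), ] <- out[as.integer(rownames(acc)), ] + acc
  }
  out / sqrt(rowSums(out^2))
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [tri_mesh()] (or any list with a `faces` matrix).
#' @return Integer matrix (n_edges x 2), each row `i < j`, with attribute
#'   `lengths` (mm) when vertex coordinates are available.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  if (!is.null(mesh$vertices)) {
    attr(e, "lengths") <- sqrt(rowSums(
      (mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE])^2))
  }
  e
}

# Single-source shortest path distances over the edge graph (Dijkstra,
# dense O(n^2) - meshes here are small).
mesh_graph_distances <- function(mesh, source) {
  e <- mesh_edges(mesh)
  len <- attr(e, "lengths")
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1]; j <- e[k, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, len[k]))
    adj[[j]] <- rbind(adj[[j]], c(i, len[k]))
  }
  dist <- rep(Inf, n)
  dist[source] <- 0
  done <- logical(n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    alt <- dist[u] + nb[, 2]
    upd <- alt < dist[nb[, 1]]
    dist[nb[upd, 1]] <- alt[upd]
  }
  dist
}
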