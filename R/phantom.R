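#' Quasi-uniform points on a sphere (Fibonacci lattice)
#'
#' @param n number of points.
#' @param radius sphere radius, mm.
#' @return n x 3 matrix of coordinates.
#' @export
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  radius * cbind(r * cos(th), r * sin(th), z)
}

#' Synthetic torso-heart phantom geometry
#'
#' Builds a concentric spherical heart and torso (optionally an ellipsoidal
#' torso), with body-surface electrodes placed quasi-uniformly on the torso
#' surface. The spherical phantom admits a closed-form forward solution
#' ([analytic_spheres_attenuation()]) used to verify the boundary-element
#' transfer matrix. Stands in for a CT-derived geometry.
#'
#' @param heart_radius epicardial sphere radius, mm.
#' @param torso_radius torso sphere radius, mm.
#' @param n_heart_nodes requested heart vertex count; rounded to the nearest
#'   geodesic icosphere size `10 f^2 + 2`. The default matches a ventricular
#'   epicardium digitized at roughly 1700 nodes.
#' @param n_torso_nodes requested torso vertex count (same rounding).
#' @param n_electrodes number of body-surface electrodes (default 200, the
#'   middle of a typical 184-216 multi-electrode setup).
#' @param conductivity homogeneous torso conductivity, S/m. The transfer
#'   matrix of a homogeneous conductor does not depend on it; stored for
#'   provenance.
#' @param torso_scale per-axis torso scale factors (ellipsoidal torso).
#' @param seed integer seed; controls the azimuthal orientation of the
#'   electrode lattice.
#' @return Object of class `torso_heart_geometry`: list with `heart`,
#'   `torso` ([tri_mesh()]s), `electrodes` (matrix, mm), `conductivity`.
#' @export
generate_phantom <- function(heart_radius = 40, torso_radius = 120,
                             n_heart_nodes = 1700, n_torso_nodes = 1000,
                             n_electrodes = 200, conductivity = 0.2,
                             torso_scale = c(1, 1, 1), seed = 1L) {
  if (heart_radius <= 0 || torso_radius <= 0) stop("geometry error: radii must be positive")
  if (heart_radius >= torso_radius * min(torso_scale))
    stop("geometry error: heart_radius must be smaller than the torso in every direction")
  if (n_heart_nodes < 4 || n_electrodes < 4) stop("geometry error: need at least 4 nodes/electrodes")
  fh <- max(1L, as.integer(round(sqrt((n_heart_nodes - 2) / 10))))
  ft <- max(1L, as.integer(round(sqrt((n_torso_nodes - 2) / 10))))
  heart <- icosphere(fh, heart_radius)
  torso <- icosphere(ft, torso_radius, scale = torso_scale)
  el <- fibonacci_sphere(n_electrodes, torso_radius)
  ang <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    stats::runif(1, 0, 2 * pi)
  })
  rot <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  el <- el %*% t(rot)
  el <- sweep(el, 2L, torso_scale, "*")
  geom <- structure(list(heart = heart, torso = torso, electrodes = el,
                         conductivity = conductivity,
                         params = list(heart_radius = heart_radius,
                                       torso_radius = torso_radius,
                                       torso_scale = torso_scale, seed = seed)),
                    class = "torso_heart_geometry")
  validate_phantom(geom)
  geom
}

# Containment + electrode-proximity invariants.
validate_phantom <- function(geom, electrode_tol = NULL) {
  hv <- geom$heart$vertices
  tv <- geom$torso$vertices
  # radial containment w.r.t. the torso centroid
  ctr <- colMeans(tv)
  hr <- sqrt(rowSums(sweep(hv, 2L, ctr)^2))
  # conservative inscribed radius of the torso mesh
  rin <- min(sqrt(rowSums(sweep(tv, 2L, ctr)^2)))
  if (max(hr) >= rin) stop("geometry error: heart vertex not strictly inside torso")
  d2 <- nearest_vertex_dist(geom$electrodes, geom$torso)
  if (is.null(electrode_tol)) {
    el <- mesh_edges(geom$torso)
    electrode_tol <- 2 * max(attr(el, "lengths"))
  }
  if (max(d2) > electrode_tol)
    stop("geometry error: electrode further than tolerance from torso surface")
  if (geom$conductivity <= 0) stop("geometry error: conductivity must be positive")
  invisible(TRUE)
}

#' @export
print.torso_heart_geometry <- function(x, ...) {
  cat(sprintf("torso-heart phantom: heart %d nodes (r=%g mm), torso %d nodes, %d electrodes\n",
              nrow(x$heart$vertices), x$params$heart_radius,
              nrow(x$torso$vertices), nrow(x$electrodes)))
  invisible(x)
}

nearest_vertex_dist <- function(points, mesh) {
  v <- mesh$vertices
  apply(points, 1L, function(p) sqrt(min(rowSums(sweep(v, 2L, p)^2))))
}

# Save/restore the global RNG so seeded helpers do not disturb user RNG flow.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}
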