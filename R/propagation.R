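#' Propagation parameters for surface beat simulation
#'
#' @param gbar node-to-node coupling strength; the conductance of an edge of
#'   length `d` mm is `gbar / d^2` so that conduction speed is controlled by a
#'   single parameter on irregular meshes (see [calibrate_gbar()]).
#' @param dt output sample interval, ms.
#' @param n_steps number of recorded samples per beat (default 550).
#' @param substeps integration substeps per output sample; `NULL` uses the
#'   cell model's default (4 for FHN, 50 for LR92).
#' @param stim_amplitude stimulus current amplitude (model units/ms); `NULL`
#'   uses the model default.
#' @param stim_duration stimulus duration, ms.
#' @param stim_onset stimulus onset time, ms.
#' @param origin index of the paced vertex; the stimulus is delivered to the
#'   vertex and its 1-ring neighbours so that capture succeeds on coarse
#'   meshes.
#' @return A list of class `propagation_params`.
#' @export
propagation_params <- function(gbar, dt = 1, n_steps = 550L, substeps = NULL,
                               stim_amplitude = NULL, stim_duration = 2,
                               stim_onset = 10, origin = 1L) {
  if (gbar < 0) stop("gbar must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 2) stop("n_steps must be >= 2")
  structure(list(gbar = gbar, dt = dt, n_steps = as.integer(n_steps),
                 substeps = substeps, stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration, stim_onset = stim_onset,
                 origin = as.integer(origin)),
            class = "propagation_params")
}

# edge list with lengths; accepts a tri_mesh or a list(vertices, edges)
get_coupling_edges <- function(mesh) {
  if (!is.null(mesh$edges)) {
    e <- as.matrix(mesh$edges)
    len <- attr(mesh$edges, "lengths")
    if (is.null(len))
      len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                             mesh$vertices[e[, 2], , drop = FALSE])^2))
    attr(e, "lengths") <- len
    return(e)
  }
  mesh_edges(mesh)
}

#' Simulate one propagating beat on a surface mesh
#'
#' Each mesh vertex carries a single-cell action-potential model; neighbouring
#' vertices exchange current `I = g (V_j - V_i)` along triangulation edges
#' with `g = gbar / d^2` (`d` = edge length). Conduction is homogeneous and
#' isotropic. Integration is explicit (forward Euler for FHN, a
#' Rush-Larsen/forward-Euler hybrid for LR92) on a substep grid finer than the
#' output sampling.
#'
#' @param mesh a [tri_mesh()], or a list with `vertices` and an `edges` matrix
#'   for non-surface coupling topologies (e.g. a 1-D test chain).
#' @param model a [cell_model()].
#' @param params a [propagation_params()].
#' @return Object of class `simulated_beat`: list with `phi_H` (n_nodes x
#'   n_steps voltage matrix, mV), `origin`, `model`, `dt` (ms), `times` (ms).
#' @export
simulate_beat <- function(mesh, model, params) {
  e <- get_coupling_edges(mesh)
  len <- attr(e, "lengths")
  n <- nrow(mesh$vertices)
  if (params$origin < 1L || params$origin > n) stop("origin vertex does not exist")
  amp <- params$stim_amplitude %||% model$default_stim_amplitude

  L <- NULL
  max_row <- 0
  if (params$gbar > 0 && nrow(e) > 0) {
    w <- params$gbar / len^2
    L <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = c(w, w), dims = c(n, n))
    rs <- Matrix::rowSums(L)
    max_row <- max(rs)
    L <- L - Matrix::Diagonal(n, rs)
  }
  # explicit-stepping stability: the coupling operator's spectral radius is
  # bounded by 2 * max row sum; keep the substep well inside 2/lambda_max
  substeps <- params$substeps %||%
    max(model$default_substeps, ceiling(params$dt * max_row * 2.5))
  dt_sub <- params$dt / substeps
  ring <- unique(c(params$origin,
                   e[e[, 1] == params$origin, 2], e[e[, 2] == params$origin, 1]))

  state <- matrix(model$rest, model$n_state, n)
  vi <- model$v_index
  out <- matrix(NA_real_, n, params$n_steps)
  stim_on <- params$stim_onset
  stim_off <- params$stim_onset + params$stim_duration
  istim <- numeric(n)
  t_sub <- 0
  for (r in seq_len(params$n_steps)) {
    out[, r] <- state[vi, ]
    for (s in seq_len(substeps)) {
      i_ext <- if (is.null(L)) numeric(n) else as.vector(L %*% state[vi, ])
      if (t_sub >= stim_on && t_sub < stim_off) {
        istim[] <- 0; istim[ring] <- amp
        i_ext <- i_ext + istim
      }
      state <- model$step(state, dt_sub, i_ext)
      t_sub <- t_sub + dt_sub
    }
    v_mv <- model$to_mv(state[vi, ])
    if (any(!is.finite(v_mv)) || any(v_mv < -150) || any(v_mv > 90))
      stop("numerical error: voltage out of bounds at t = ", r * params$dt,
           " ms; reduce the integration step (increase substeps)")
  }
  phi <- model$to_mv(out)
  structure(list(phi_H = phi, origin = params$origin, model = model$name,
                 dt = params$dt, times = (seq_len(params$n_steps) - 1) * params$dt,
                 gbar = params$gbar),
            class = "simulated_beat")
}

#' @export
print.simulated_beat <- function(x, ...) {
  cat(sprintf("simulated beat (%s): %d nodes x %d samples, origin vertex %d, dt = %g ms\n",
              x$model, nrow(x$phi_H), ncol(x$phi_H), x$origin, x$dt))
  invisible(x)
}

#' Threshold-crossing activation times of a simulated beat
#'
#' First upward crossing of a voltage threshold per node; `NA` for nodes that
#' never activate. This is the simulator-side ground truth used for coupling
#' calibration, distinct from the electrogram-based estimators in the
#' post-processing module.
#'
#' @param beat a [simulate_beat()] result or a voltage matrix in mV.
#' @param threshold_mv threshold, mV.
#' @param dt sample interval, ms (taken from the beat when available).
#' @return numeric vector of activation times, ms.
#' @export
beat_activation_times <- function(beat, threshold_mv = -40, dt = NULL) {
  phi <- if (inherits(beat, "simulated_beat")) beat$phi_H else as.matrix(beat)
  dt <- dt %||% (if (inherits(beat, "simulated_beat")) beat$dt else 1)
  idx <- apply(phi > threshold_mv, 1L, function(z) {
    i <- which(z)
    if (length(i)) i[1] else NA_integer_
  })
  (idx - 1L) * dt
}

#' Calibrate the coupling strength for a target activation spread
#'
#' Bisects `gbar` (log scale) until the difference between the last and first
#' nodal activation time of a paced beat falls inside `target_spread`. The
#' spread decreases monotonically with `gbar` over the bracket (stronger
#' coupling, faster conduction), so the default window of 60-100 ms
#' reproduces an orderly full activation followed by full recovery.
#'
#' @param mesh a [tri_mesh()].
#' @param model a [cell_model()].
#' @param target_spread numeric length-2 window (ms) for total activation
#'   spread.
#' @param bracket positive `c(lo, hi)` bracket for `gbar`.
#' @param origin paced vertex used during calibration.
#' @param n_steps samples simulated per probe beat.
#' @param dt sample interval, ms.
#' @param max_iter bisection iterations.
#' @return calibrated `gbar`, with the achieved spread (ms) as attribute
#'   `spread`.
#' @export
calibrate_gbar <- function(mesh, model, target_spread = c(60, 100),
                           bracket = c(0.05, 20), origin = 1L,
                           n_steps = 500L, dt = 1, max_iter = 30L) {
  if (length(bracket) != 2 || bracket[1] <= 0 || bracket[2] <= bracket[1])
    stop("calibration error: invalid gbar bracket")
  if (target_spread[1] >= target_spread[2]) stop("invalid target window")
  spread_at <- function(g) {
    beat <- simulate_beat(mesh, model,
                          propagation_params(g, dt = dt, n_steps = n_steps, origin = origin))
    at <- beat_activation_times(beat)
    if (anyNA(at)) return(Inf)
    diff(range(at))
  }
  lo <- bracket[1]; hi <- bracket[2]
  s_lo <- spread_at(lo)
  s_hi <- spread_at(hi)
  if (s_lo < target_spread[1])
    stop("calibration error: spread already below window at the lower bracket")
  if (s_hi > target_spread[2])
    stop("calibration error: window unreachable within bracket (spread ",
         signif(s_hi, 3), " ms at gbar = ", hi, ")")
  if (s_lo <= target_spread[2]) return(structure(lo, spread = s_lo))
  if (s_hi >= target_spread[1]) return(structure(hi, spread = s_hi))
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    s <- spread_at(mid)
    if (s >= target_spread[1] && s <= target_spread[2])
      return(structure(mid, spread = s))
    if (s > target_spread[2]) lo <- mid else hi <- mid
  }
  stop("calibration error: bisection did not reach the target window")
}

#' Partition a heart mesh into LV, RV and base/apex regions
#'
#' Geometric stand-in for an anatomical labelling: polar caps along the
#' declared base-apex axis (top `base_frac`, bottom `apex_frac` of the axial
#' extent) are labelled `BASE_APEX`; the remaining band is split into two
#' longitudinal sectors, `LV` and `RV`.
#'
#' @param mesh a [tri_mesh()] with sphere topology.
#' @param axis base-apex axis (base towards `+axis`).
#' @param ref reference direction defining zero longitude; must be rotated
#'   together with `axis` for labels to be invariant under rigid rotation.
#'   Defaults to a fixed perpendicular of `axis`.
#' @param base_frac,apex_frac axial fractions assigned to the polar caps.
#' @return factor of length n_vertices with levels `LV`, `RV`, `BASE_APEX`.
#' @export
label_regions <- function(mesh, axis = c(0, 0, 1), ref = NULL,
                          base_frac = 0.2, apex_frac = 0.1) {
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(ref)) {
    seed_vec <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ref <- seed_vec - sum(seed_vec * axis) * axis
  } else {
    ref <- ref - sum(ref * axis) * axis
  }
  if (sum(ref^2) < 1e-12) stop("ref must not be parallel to axis")
  e1 <- ref / sqrt(sum(ref^2))
  e2 <- cross3(axis, e1)
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  z <- as.vector(vc %*% axis)
  zn <- (z - min(z)) / (max(z) - min(z))
  lon <- atan2(as.vector(vc %*% e2), as.vector(vc %*% e1))
  lab <- ifelse(zn > 1 - base_frac | zn < apex_frac, "BASE_APEX",
                ifelse(lon >= 0, "LV", "RV"))
  out <- factor(lab, levels = c("LV", "RV", "BASE_APEX"))
  if (any(tabulate(out, 3L) == 0L)) stop("region labelling produced an empty region")
  attr(out, "axis") <- axis
  out
}

#' Sample beat-origin vertices within a region
#'
#' Draws `n` distinct vertices of the requested region pseudo-randomly with a
#' minimum pairwise spacing (greedy rejection sampling), emulating a roughly
#' uniform, equidistant distribution of pacing sites. If the spacing is
#' infeasible it is reduced by 20% steps with a warning.
#'
#' @param labels region labels from [label_regions()].
#' @param mesh the labelled [tri_mesh()].
#' @param region `"LV"`, `"RV"`, `"BASE_APEX"` or `"ALL"`.
#' @param n number of origins (default 50 per region).
#' @param min_spacing minimum pairwise distance, mm; default
#'   `0.5 * sqrt(region_area / n)`.
#' @param seed integer seed; sampling is deterministic per seed.
#' @return integer vector of vertex indices.
#' @export
choose_beat_origins <- function(labels, mesh, region = "ALL", n = 50L,
                                min_spacing = NULL, seed = 1L) {
  region <- match.arg(region, c("ALL", "LV", "RV", "BASE_APEX"))
  cand <- if (region == "ALL") seq_along(labels) else which(labels == region)
  if (length(cand) == 0L) stop("sampling error: region is empty")
  if (n > length(cand))
    stop("sampling error: n = ", n, " exceeds region vertex count ", length(cand))
  if (is.null(min_spacing)) {
    area <- sum(mesh_vertex_areas(mesh)[cand])
    min_spacing <- 0.5 * sqrt(area / n)
  }
  v <- mesh$vertices
  ord <- with_seed(seed, sample(cand))
  spacing <- min_spacing
  repeat {
    chosen <- integer(0)
    for (i in ord) {
      if (length(chosen) == 0L ||
          min(sqrt(rowSums(sweep(v[chosen, , drop = FALSE], 2L, v[i, ])^2))) >= spacing) {
        chosen <- c(chosen, i)
        if (length(chosen) == n) return(chosen)
      }
    }
    spacing <- spacing * 0.8
    warning("min_spacing infeasible; reduced to ", signif(spacing, 3), " mm")
    if (spacing < 1e-6) return(ord[seq_len(n)])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
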