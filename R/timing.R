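#' Analysis windows for activation and recovery mapping
#'
#' @param qrs QRS (depolarization) window, `c(onset, offset)` in ms.
#' @param t_wave T-wave (repolarization) window, `c(onset, offset)` in ms.
#' @return Object of class `analysis_windows`.
#' @export
analysis_windows <- function(qrs, t_wave) {
  if (length(qrs) != 2 || length(t_wave) != 2) stop("windows must be length-2")
  if (qrs[1] >= qrs[2] || t_wave[1] >= t_wave[2]) stop("degenerate window")
  if (qrs[2] > t_wave[1]) stop("QRS window must precede the T-wave window")
  structure(list(qrs = as.numeric(qrs), t_wave = as.numeric(t_wave)),
            class = "analysis_windows")
}

#' @export
print.analysis_windows <- function(x, ...) {
  cat(sprintf("analysis windows: QRS [%g, %g] ms, T wave [%g, %g] ms\n",
              x$qrs[1], x$qrs[2], x$t_wave[1], x$t_wave[2]))
  invisible(x)
}

#' Estimate QRS and T-wave windows from a potential record
#'
#' Computes the RMS over nodes of the spatially de-meaned potentials,
#' thresholds it at a fraction of its peak, and takes the first sustained
#' suprathreshold run as the QRS window and the next as the T-wave window.
#' When depolarization and repolarization merge into a single run (as happens
#' for action-potential-shaped records whose plateau keeps the spatial spread
#' above threshold), the run is split at its interior minimum between the two
#' dominant peaks. Both windows can be overridden.
#'
#' @param phi potential matrix, nodes x timesteps (mV).
#' @param dt sample interval, ms.
#' @param threshold fraction of the RMS peak (default 0.1).
#' @param min_run minimum run length, samples (default 5).
#' @param qrs,t_wave manual overrides (`c(onset, offset)` ms); when both are
#'   given they are returned as-is.
#' @return An [analysis_windows()] object.
#' @export
estimate_windows <- function(phi, dt = 1, threshold = 0.1, min_run = 5L,
                             qrs = NULL, t_wave = NULL) {
  if (!is.null(qrs) && !is.null(t_wave)) return(analysis_windows(qrs, t_wave))
  phi <- as.matrix(phi)
  dev <- sweep(phi, 2L, colMeans(phi))
  s <- sqrt(colMeans(dev^2))
  pk <- max(s)
  if (pk <= 0) stop("windowing error: record has no spatial signal")
  above <- s > threshold * pk
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_run)
  if (length(runs) == 0L) stop("windowing error: no sustained threshold crossing")
  to_ms <- function(i) (i - 1) * dt
  if (length(runs) >= 2L) {
    q <- c(to_ms(starts[runs[1]]), to_ms(ends[runs[1]]))
    # among later runs take the one with the largest peak
    later <- runs[-1]
    pks <- vapply(later, function(k) max(s[starts[k]:ends[k]]), numeric(1))
    k <- later[which.max(pks)]
    tw <- c(to_ms(starts[k]), to_ms(ends[k]))
  } else {
    k <- runs[1]
    seg <- s[starts[k]:ends[k]]
    split <- split_two_peaks(seg)
    if (is.na(split)) stop("windowing error: single run without separable peaks")
    mid <- starts[k] + split - 1L
    q <- c(to_ms(starts[k]), to_ms(mid))
    tw <- c(to_ms(mid), to_ms(ends[k]))
  }
  analysis_windows(qrs %||% q, t_wave %||% tw)
}

# index of the interior minimum between the two most prominent peaks of a
# positive curve, NA if no two separated peaks exist
split_two_peaks <- function(seg) {
  n <- length(seg)
  if (n < 5L) return(NA_integer_)
  i_max <- which.max(seg)
  # best valley/second-peak pair on either side of the global peak
  best <- NA_integer_; best_prom <- 0
  for (side in c("left", "right")) {
    idx <- if (side == "left") seq_len(max(i_max - 1L, 1L)) else i_max:n
    if (length(idx) < 3L) next
    sub <- seg[idx]
    if (side == "left") {
      # valley after the secondary peak
      for (v in 2:(length(sub) - 1L)) {
        peak2 <- max(sub[1:v])
        prom <- min(peak2, seg[i_max]) - sub[v]
        if (sub[v] < 0.7 * peak2 && prom > best_prom) { best <- idx[v]; best_prom <- prom }
      }
    } else {
      for (v in 2:(length(sub) - 1L)) {
        peak2 <- max(sub[v:length(sub)])
        prom <- min(peak2, seg[i_max]) - sub[v]
        if (sub[v] < 0.7 * peak2 && prom > best_prom) { best <- idx[v]; best_prom <- prom }
      }
    }
  }
  best
}

window_indices <- function(window, n, dt) {
  i0 <- max(1L, floor(window[1] / dt) + 1L)
  i1 <- min(n, floor(window[2] / dt) + 1L)
  if (i0 > i1) stop("window is empty for this record")
  i0:i1
}

#' Temporal activation and recovery times of one electrogram
#'
#' The temporal-only criteria: activation is the instant of steepest
#' downslope (most negative forward difference) inside the QRS window, and
#' recovery the instant of steepest upslope inside the T-wave window. The
#' derivative is assigned to the earlier sample; ties take the earliest
#' instant. For action-potential-shaped signals, which deflect upward when
#' the wavefront arrives, set `polarity = "ap"` to mirror both criteria.
#'
#' @param egm potential series at one node (mV); at least 3 samples.
#' @param dt sample interval, ms.
#' @param windows an [analysis_windows()] object, or `c(onset, offset)` ms for
#'   the relevant window.
#' @param polarity `"electrogram"` (default) or `"ap"`.
#' @param smooth_window odd number of samples for a Savitzky-style (local
#'   linear) derivative estimate; 1 (default) uses plain forward differences
#'   assigned to the earlier sample. Smoothing is intended for noisy
#'   reconstructed electrograms.
#' @param interpolate refine the extremum to sub-sample precision by parabolic
#'   interpolation (default `FALSE`, keeping the sample-aligned, earliest-tie
#'   convention).
#' @return time in ms, or `NA` with attribute `undefined = TRUE` when no
#'   deflection of the required sign exists in the window.
#' @export
activation_time_temporal <- function(egm, dt = 1, windows,
                                     polarity = c("electrogram", "ap"),
                                     smooth_window = 1L, interpolate = FALSE) {
  polarity <- match.arg(polarity)
  w <- if (inherits(windows, "analysis_windows")) windows$qrs else windows
  extremum_slope_time(egm, dt, w,
                      direction = if (polarity == "electrogram") -1 else 1,
                      smooth_window = smooth_window, interpolate = interpolate)
}

#' @rdname activation_time_temporal
#' @export
recovery_time_temporal <- function(egm, dt = 1, windows,
                                   polarity = c("electrogram", "ap"),
                                   smooth_window = 1L, interpolate = FALSE) {
  polarity <- match.arg(polarity)
  w <- if (inherits(windows, "analysis_windows")) windows$t_wave else windows
  extremum_slope_time(egm, dt, w,
                      direction = if (polarity == "electrogram") 1 else -1,
                      smooth_window = smooth_window, interpolate = interpolate)
}

# centered local-linear (ramp-kernel) derivative; window = 1 falls back to
# forward differences at the earlier sample
series_derivative <- function(egm, dt, smooth_window = 1L) {
  if (smooth_window <= 1L) return(diff(egm) / dt)
  if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
  half <- smooth_window %/% 2L
  kern <- seq(-half, half)
  kern <- kern / (sum(kern^2) * dt)
  as.numeric(stats::filter(egm, rev(kern), sides = 2))
}

extremum_slope_time <- function(egm, dt, window, direction,
                                smooth_window = 1L, interpolate = FALSE) {
  egm <- as.numeric(egm)
  if (length(egm) < 3L) stop("electrogram must have at least 3 samples")
  if (any(!is.finite(egm))) stop("non-finite electrogram")
  d <- series_derivative(egm, dt, smooth_window)
  idx <- window_indices(window, length(d), dt)
  v <- direction * d[idx]
  v[is.na(v)] <- -Inf
  if (max(v) <= 0) return(structure(NA_real_, undefined = TRUE))
  j <- which.max(v)
  tau <- (idx[j] - 1L) * dt
  if (interpolate && j > 1L && j < length(v) &&
      is.finite(v[j - 1]) && is.finite(v[j + 1])) {
    den <- v[j - 1] - 2 * v[j] + v[j + 1]
    if (den < 0) tau <- tau + 0.5 * (v[j - 1] - v[j + 1]) / den * dt
  }
  tau
}

#' Surface gradient operator of a triangle mesh
#'
#' Per-triangle linear-interpolation gradients averaged onto vertices with
#' area weights. Applied to a potential field it yields the per-node spatial
#' gradient magnitude used by the spatiotemporal timing criterion; a constant
#' field maps to zero exactly.
#'
#' @param mesh a [tri_mesh()].
#' @return Object of class `gradient_operator`.
#' @export
spatial_gradient_operator <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nf <- nrow(f); n <- nrow(v)
  fn_raw <- mesh_face_normals_raw(mesh)
  a2 <- sqrt(rowSums(fn_raw^2))          # 2 * area
  nrm <- fn_raw / a2
  # grad of hat function at vertex k: (n x opposite_edge) / (2A)
  ii <- jj <- integer(3L * nf)
  xs <- list(numeric(3L * nf), numeric(3L * nf), numeric(3L * nf))
  for (k in 1:3) {
    opp1 <- f[, c(2, 3, 1)[k]]
    opp2 <- f[, c(3, 1, 2)[k]]
    edge <- v[opp2, , drop = FALSE] - v[opp1, , drop = FALSE]
    g <- cbind(nrm[, 2] * edge[, 3] - nrm[, 3] * edge[, 2],
               nrm[, 3] * edge[, 1] - nrm[, 1] * edge[, 3],
               nrm[, 1] * edge[, 2] - nrm[, 2] * edge[, 1]) / a2
    sl <- (k - 1L) * nf + seq_len(nf)
    ii[sl] <- seq_len(nf)
    jj[sl] <- f[, k]
    for (d in 1:3) xs[[d]][sl] <- g[, d]
  }
  G <- lapply(1:3, function(d)
    Matrix::sparseMatrix(i = ii, j = jj, x = xs[[d]], dims = c(nf, n)))
  fa <- a2 / 2
  # area-weighted face-to-vertex averaging
  W <- Matrix::sparseMatrix(i = c(f), j = rep(seq_len(nf), 3L),
                            x = rep(fa / 3, 3L), dims = c(n, nf))
  W <- Matrix::Diagonal(n, 1 / Matrix::rowSums(W)) %*% W
  structure(list(Gx = G[[1]], Gy = G[[2]], Gz = G[[3]], W = W,
                 n_vertices = n, n_faces = nf),
            class = "gradient_operator")
}

#' @rdname spatial_gradient_operator
#' @param op a `gradient_operator`.
#' @param phi potential field: vector (one instant) or nodes x timesteps
#'   matrix.
#' @return per-node gradient magnitude, same time layout as `phi` (mV/mm).
#' @export
gradient_magnitude <- function(op, phi) {
  phi <- as.matrix(phi)
  gx <- as.matrix(op$Gx %*% phi)
  gy <- as.matrix(op$Gy %*% phi)
  gz <- as.matrix(op$Gz %*% phi)
  out <- as.matrix(op$W %*% sqrt(gx^2 + gy^2 + gz^2))
  out
}

#' Spatiotemporal activation/recovery time maps
#'
#' The spatiotemporal criterion marks wavefront passage at a node as the
#' instant extremizing the product of the node's spatial gradient magnitude
#' and its temporal derivative: for electrogram polarity the product is most
#' negative when a depolarization front passes (activation = arg-min over the
#' QRS window) and most positive during repolarization (recovery = arg-max
#' over the T-wave window); for AP polarity the signs mirror. Nodes whose
#' spatial gradient stays below `1e-6` of the global maximum throughout the
#' window fall back to the temporal-only estimate and are flagged.
#'
#' @param phi_H potential matrix, nodes x timesteps (mV).
#' @param mesh the heart [tri_mesh()] (or a precomputed
#'   [spatial_gradient_operator()]).
#' @param windows an [analysis_windows()] object.
#' @param dt sample interval, ms.
#' @param polarity `"electrogram"` or `"ap"`.
#' @param smooth_window,interpolate see [activation_time_temporal()].
#' @return list with `tau` (ms per node) and `fallback` (logical per node).
#' @export
activation_time_spatiotemporal <- function(phi_H, mesh, windows, dt = 1,
                                           polarity = c("electrogram", "ap"),
                                           smooth_window = 1L,
                                           interpolate = FALSE) {
  polarity <- match.arg(polarity)
  spatiotemporal_times(phi_H, mesh, windows$qrs, dt,
                       direction = if (polarity == "electrogram") -1 else 1,
                       temporal_fun = activation_time_temporal,
                       windows = windows, polarity = polarity,
                       smooth_window = smooth_window, interpolate = interpolate)
}

#' @rdname activation_time_spatiotemporal
#' @export
recovery_time_spatiotemporal <- function(phi_H, mesh, windows, dt = 1,
                                         polarity = c("electrogram", "ap"),
                                         smooth_window = 1L,
                                         interpolate = FALSE) {
  polarity <- match.arg(polarity)
  spatiotemporal_times(phi_H, mesh, windows$t_wave, dt,
                       direction = if (polarity == "electrogram") 1 else -1,
                       temporal_fun = recovery_time_temporal,
                       windows = windows, polarity = polarity,
                       smooth_window = smooth_window, interpolate = interpolate)
}

spatiotemporal_times <- function(phi_H, mesh, window, dt, direction,
                                 temporal_fun, windows, polarity,
                                 smooth_window = 1L, interpolate = FALSE) {
  phi_H <- as.matrix(phi_H)
  op <- if (inherits(mesh, "gradient_operator")) mesh else spatial_gradient_operator(mesh)
  if (nrow(phi_H) != op$n_vertices) stop("phi_H rows must match mesh vertices")
  gm <- gradient_magnitude(op, phi_H)
  if (smooth_window <= 1L) {
    dphi <- (phi_H[, -1L, drop = FALSE] - phi_H[, -ncol(phi_H), drop = FALSE]) / dt
  } else {
    dphi <- t(apply(phi_H, 1L, series_derivative, dt = dt,
                    smooth_window = smooth_window))
  }
  idx <- window_indices(window, ncol(dphi), dt)
  prod <- gm[, idx, drop = FALSE] * dphi[, idx, drop = FALSE] * direction
  prod[is.na(prod)] <- -Inf
  gmax <- max(gm)
  fallback <- apply(gm[, idx, drop = FALSE], 1L, max) <= 1e-6 * gmax
  n <- nrow(phi_H)
  tau <- numeric(n)
  for (i in seq_len(n)) {
    pv <- prod[i, ]
    j <- which.max(pv)
    t_i <- (idx[j] - 1L) * dt
    if (interpolate && j > 1L && j < length(pv) &&
        is.finite(pv[j - 1]) && is.finite(pv[j + 1])) {
      den <- pv[j - 1] - 2 * pv[j] + pv[j + 1]
      if (is.finite(den) && den < 0)
        t_i <- t_i + 0.5 * (pv[j - 1] - pv[j + 1]) / den * dt
    }
    tau[i] <- t_i
  }
  if (any(fallback)) {
    for (i in which(fallback)) {
      tau[i] <- temporal_fun(phi_H[i, ], dt, windows, polarity,
                             smooth_window = smooth_window,
                             interpolate = interpolate)
    }
  }
  list(tau = tau, fallback = fallback)
}

#' Per-node timing map of a reconstructed or simulated beat
#'
#' Convenience wrapper computing activation and recovery times for every node
#' with either the temporal-only or the spatiotemporal criterion.
#'
#' @param phi_H potential matrix, nodes x timesteps (mV).
#' @param dt sample interval, ms.
#' @param windows an [analysis_windows()] object (or `NULL` to estimate).
#' @param method `"temporal"` or `"spatiotemporal"`.
#' @param mesh required for the spatiotemporal criterion.
#' @param polarity `"electrogram"` or `"ap"`.
#' @param smooth_window,interpolate see [activation_time_temporal()].
#' @return data.frame of class `timing_map` with columns `vertex`,
#'   `tau_act_ms`, `tau_rec_ms`, `fallback`; attribute `method`.
#' @export
compute_timing_map <- function(phi_H, dt = 1, windows = NULL,
                               method = c("temporal", "spatiotemporal"),
                               mesh = NULL, polarity = c("electrogram", "ap"),
                               smooth_window = 1L, interpolate = FALSE) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  phi_H <- as.matrix(phi_H)
  if (is.null(windows)) windows <- estimate_windows(phi_H, dt)
  n <- nrow(phi_H)
  if (method == "temporal") {
    act <- vapply(seq_len(n), function(i)
      as.numeric(activation_time_temporal(phi_H[i, ], dt, windows, polarity,
                                          smooth_window, interpolate)), numeric(1))
    rec <- vapply(seq_len(n), function(i)
      as.numeric(recovery_time_temporal(phi_H[i, ], dt, windows, polarity,
                                        smooth_window, interpolate)), numeric(1))
    fb <- rep(FALSE, n)
  } else {
    if (is.null(mesh)) stop("spatiotemporal criterion requires the mesh")
    a <- activation_time_spatiotemporal(phi_H, mesh, windows, dt, polarity,
                                        smooth_window, interpolate)
    r <- recovery_time_spatiotemporal(phi_H, mesh, windows, dt, polarity,
                                      smooth_window, interpolate)
    act <- a$tau; rec <- r$tau; fb <- a$fallback | r$fallback
  }
  out <- data.frame(vertex = seq_len(n), tau_act_ms = act, tau_rec_ms = rec,
                    fallback = fb)
  attr(out, "method") <- method
  attr(out, "windows") <- windows
  class(out) <- c("timing_map", "data.frame")
  out
}

#' Locate the beat origin as the earliest-activation vertex
#'
#' @param timing a [compute_timing_map()] result, or a numeric vector of
#'   activation times (ms, `NA` = undefined).
#' @return vertex index of the minimum activation time (ties: lowest index).
#' @export
localize_origin <- function(timing) {
  tau <- if (inherits(timing, "timing_map")) timing$tau_act_ms else as.numeric(timing)
  if (all(is.na(tau))) stop("no defined activation times")
  which.min(tau)
}

#' Localization error between predicted and true pacing site
#'
#' @param pred predicted vertex index.
#' @param truth true pacing location: a vertex index (when `truth_is_vertex`)
#'   or a 3D point (mm).
#' @param mesh the heart [tri_mesh()].
#' @param method `"euclidean"` (default) or `"geodesic"` (graph shortest path
#'   along mesh edges).
#' @param truth_is_vertex interpret `truth` as a vertex index.
#' @return distance in mm.
#' @export
localization_error <- function(pred, truth, mesh,
                               method = c("euclidean", "geodesic"),
                               truth_is_vertex = length(truth) == 1L) {
  method <- match.arg(method)
  p_pred <- mesh$vertices[pred, ]
  if (truth_is_vertex) {
    tv <- as.integer(truth)
    p_true <- mesh$vertices[tv, ]
  } else {
    p_true <- as.numeric(truth)
  }
  if (method == "euclidean") return(sqrt(sum((p_pred - p_true)^2)))
  if (!truth_is_vertex) tv <- match_electrodes_to_nodes(matrix(p_true, 1L), mesh)
  mesh_graph_distances(mesh, pred)[tv]
}
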