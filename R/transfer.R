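#' Analytic attenuation of spherical harmonics in a concentric annulus
#'
#' Closed-form solution of the Laplace equation between concentric spheres of
#' radii `a < b`, with a degree-`l` spherical harmonic prescribed on the inner
#' sphere and zero normal flux on the outer sphere. The body-surface pattern
#' is the same harmonic attenuated by the returned factor. Serves as the
#' independent oracle for the boundary-element transfer matrix.
#'
#' @param l spherical-harmonic degree (integer >= 0).
#' @param a inner (heart) radius, mm.
#' @param b outer (torso) radius, mm.
#' @return Attenuation factor (dimensionless).
#' @examples
#' analytic_spheres_attenuation(0, 1, 2)  # 1: constants pass unattenuated
#' analytic_spheres_attenuation(1, 1, 2)  # 0.6
#' @export
analytic_spheres_attenuation <- function(l, a, b) {
  if (a <= 0 || a >= b) stop("domain error: need 0 < a < b")
  if (l < 0 || l != round(l)) stop("domain error: l must be a non-negative integer")
  (2 * l + 1) * a^(l + 1) * b^l / ((l + 1) * a^(2 * l + 1) + l * b^(2 * l + 1))
}

#' Heart-to-body transfer matrix by the boundary element method
#'
#' Computes the linear map `A` from epicardial-node potentials to
#' body-surface-electrode potentials for the source-free homogeneous volume
#' between the two closed surfaces, with a zero-flux (insulating) boundary
#' condition on the torso. Discretization is vertex collocation with
#' piecewise-constant elements weighted by the barycentric dual area; the
#' singular double-layer diagonal is fixed by the solid-angle (row-sum)
#' identity, which makes a spatially constant heart potential map to the same
#' constant at every body point exactly. Electrode values are taken at the
#' nearest torso vertex.
#'
#' @param geometry a [generate_phantom()] result or any `torso_heart_geometry`.
#' @param electrodes optional electrode coordinate matrix overriding
#'   `geometry$electrodes`; pass `geometry$torso$vertices` to obtain the map
#'   to every torso node.
#' @return Object of class `transfer_matrix`: list with `A`
#'   (n_electrodes x n_heart_nodes, dimensionless), `electrode_nodes`
#'   (torso vertex index per electrode), `A_torso` (full torso map).
#' @export
compute_transfer_matrix <- function(geometry, electrodes = NULL) {
  heart <- geometry$heart
  torso <- geometry$torso
  validate_tri_mesh(heart, require_sphere = TRUE)
  validate_tri_mesh(torso, require_sphere = TRUE)
  if (is.null(electrodes)) electrodes <- geometry$electrodes

  nh <- nrow(heart$vertices)
  nb <- nrow(torso$vertices)
  pts <- rbind(torso$vertices, heart$vertices)
  # out-of-volume normals: outward on the torso, into the heart on the heart
  nrm <- rbind(mesh_vertex_normals(torso), -mesh_vertex_normals(heart))
  ar <- c(mesh_vertex_areas(torso), mesh_vertex_areas(heart))
  n <- nb + nh

  # K_ij = a_j n_j.(r_i - x_j)/R^3 (double layer), G_ij = a_j / R (single layer)
  K <- matrix(0, n, n)
  G <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- pts - matrix(pts[j, ], n, 3L, byrow = TRUE)
    r2 <- d[, 1]^2 + d[, 2]^2 + d[, 3]^2
    r1 <- sqrt(r2)
    kj <- ar[j] * (d %*% nrm[j, ]) / (r2 * r1)
    kj[j] <- 0
    K[, j] <- kj
    gj <- ar[j] / r1
    gj[j] <- 2 * sqrt(pi * ar[j])  # flat-disk limit of the 1/R self-integral
    G[, j] <- gj
  }
  # auto solid angle: a constant potential with zero flux must satisfy the BIE
  diag(K) <- 2 * pi - rowSums(K)

  iB <- seq_len(nb)
  iH <- nb + seq_len(nh)
  # unknowns [Phi_B; Gamma_H]; Gamma_H is the heart-surface normal gradient
  M <- matrix(0, n, n)
  M[iB, iB] <- diag(2 * pi, nb) - K[iB, iB]
  M[iH, iB] <- -K[iH, iB]
  M[iB, nb + seq_len(nh)] <- G[iB, iH]
  M[iH, nb + seq_len(nh)] <- G[iH, iH]
  rhs <- rbind(K[iB, iH], K[iH, iH] - diag(2 * pi, nh))
  sol <- tryCatch(solve(M, rhs),
                  error = function(e) stop("numerical error: singular BEM system (", conditionMessage(e), ")"))
  A_torso <- sol[iB, , drop = FALSE]

  idx <- match_electrodes_to_nodes(electrodes, torso)
  A <- A_torso[idx, , drop = FALSE]
  dev <- max(abs(rowSums(A) - 1))
  if (dev > 1e-3)
    warning("transfer matrix row sums deviate from 1 by ", signif(dev, 3))
  structure(list(A = A, electrode_nodes = idx, A_torso = A_torso,
                 n_heart = nh, n_torso = nb, row_sum_dev = dev),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer matrix: %d electrodes x %d heart nodes (max |rowsum-1| = %.2e)\n",
              nrow(x$A), ncol(x$A), x$row_sum_dev))
  invisible(x)
}

#' @export
as.matrix.transfer_matrix <- function(x, ...) x$A

#' Nearest mesh vertex for each query point
#'
#' Euclidean nearest-vertex matching, ties broken by the lowest vertex index.
#' Used to pair electrodes with epicardial or torso nodes.
#'
#' @param points query points (m x 3).
#' @param mesh a [tri_mesh()].
#' @return integer vector of vertex indices (1-based).
#' @export
match_electrodes_to_nodes <- function(points, mesh) {
  points <- matrix(points, ncol = 3L)
  if (nrow(points) == 0L || nrow(mesh$vertices) == 0L) stop("empty points or mesh")
  v <- mesh$vertices
  vv <- rowSums(v^2)
  # squared distance via |v|^2 - 2 v.p + |p|^2; the |p|^2 term is constant per row
  d2 <- outer(vv, rep(1, nrow(points))) - 2 * v %*% t(points)
  apply(d2, 2L, which.min)
}

#' Forward projection of epicardial potentials to the body surface
#'
#' Applies the transfer matrix to an epicardial potential series and
#' optionally adds zero-mean Gaussian sensor noise per electrode, scaled to a
#' requested signal-to-noise ratio.
#'
#' @param A a [compute_transfer_matrix()] result or plain matrix.
#' @param phi_H epicardial potentials, n_heart_nodes x n_timesteps (mV).
#' @param snr_db target SNR in dB (`NULL` for noiseless). Noise power is set
#'   per electrode from that electrode's mean squared signal.
#' @param seed integer seed for the noise (required when `snr_db` is set).
#' @param dt sample interval, ms.
#' @return Object of class `body_potentials`: list with `phi_B`
#'   (n_electrodes x n_timesteps, mV), `dt`, `snr_db`.
#' @export
forward_project <- function(A, phi_H, snr_db = NULL, seed = 1L, dt = 1) {
  Am <- if (inherits(A, "transfer_matrix")) A$A else as.matrix(A)
  phi_H <- as.matrix(phi_H)
  if (ncol(Am) != nrow(phi_H))
    stop("shape error: ncol(A) = ", ncol(Am), " but nrow(phi_H) = ", nrow(phi_H))
  phi_B <- Am %*% phi_H
  if (!is.null(snr_db)) {
    sig_pow <- rowMeans(phi_B^2)
    noise_sd <- sqrt(sig_pow / 10^(snr_db / 10))
    noise <- with_seed(seed, matrix(stats::rnorm(length(phi_B)), nrow(phi_B)) * noise_sd)
    phi_B <- phi_B + noise
  }
  body_potentials(phi_B, dt = dt, snr_db = snr_db)
}

#' Temporal low-pass filtering of body-surface potentials
#'
#' Centered moving average per electrode, the usual band-limiting step before
#' inversion (recorded body-surface potentials are always low-pass filtered;
#' unfiltered white sensor noise destabilizes per-instant regularization).
#' Edges use the partial window.
#'
#' @param phi_B a [forward_project()] result or electrode x time matrix.
#' @param window window length in samples (odd; 1 = no filtering).
#' @return same type as the input, filtered.
#' @export
smooth_body_potentials <- function(phi_B, window = 5L) {
  if (window <= 1L) return(phi_B)
  if (window %% 2L == 0L) stop("window must be odd")
  m <- if (inherits(phi_B, "body_potentials")) phi_B$phi_B else as.matrix(phi_B)
  half <- window %/% 2L
  nt <- ncol(m)
  cs <- cbind(0, t(apply(m, 1L, cumsum)))
  lo <- pmax(seq_len(nt) - half, 1L)
  hi <- pmin(seq_len(nt) + half, nt)
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    matrix(hi - lo + 1L, nrow(m), nt, byrow = TRUE)
  if (inherits(phi_B, "body_potentials")) {
    phi_B$phi_B <- out
    phi_B
  } else out
}

body_potentials <- function(phi_B, dt = 1, snr_db = NULL) {
  if (dt <= 0) stop("dt must be positive")
  structure(list(phi_B = as.matrix(phi_B), dt = dt, snr_db = snr_db),
            class = "body_potentials")
}

#' @export
print.body_potentials <- function(x, ...) {
  cat(sprintf("body potentials: %d electrodes x %d samples (dt = %g ms%s)\n",
              nrow(x$phi_B), ncol(x$phi_B), x$dt,
              if (is.null(x$snr_db)) "" else sprintf(", SNR %g dB", x$snr_db)))
  invisible(x)
}
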