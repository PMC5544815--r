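#' Configuration of the synthetic end-to-end benchmark
#'
#' Collects every knob of the phantom experiment: geometry, cell model, beat
#' origins, SVD basis, noise, inverse-solver settings and seeds. Defaults are
#' the package's desk-scale study conditions: a 40 mm spherical heart inside a
#' 120 mm torso, 812 heart nodes, 200 body-surface electrodes, 103 epicardial
#' evaluation sites (two circumferential bands of 99 plus 4 apical), 550
#' samples per beat at 1 ms, 50 simulated origins per region and additive
#' 30 dB sensor noise.
#'
#' @param heart_radius,torso_radius phantom radii, mm.
#' @param n_heart_nodes,n_torso_nodes,n_electrodes phantom discretization.
#' @param conductivity homogeneous conductivity, S/m (provenance only).
#' @param cell_model `"fhn"` or `"lr92"`.
#' @param origins_per_region simulated beat origins per region (LV, RV,
#'   base/apex).
#' @param components SVD component range `c(first, last)` of the truncated
#'   basis (1-based; default 2-10).
#' @param n_test_beats held-out test beats, paced from vertices disjoint from
#'   every basis origin.
#' @param test_regions regions the test beats are paced from.
#' @param snr_db sensor SNR of the synthetic body-surface recordings (dB).
#' @param dt,n_steps sampling of each simulated beat (ms, samples).
#' @param target_spread activation-spread window (ms) for [calibrate_gbar()].
#' @param folds cross-validation folds for the PBR budget.
#' @param n_eval_sites epicardial evaluation sites (band electrodes + apex).
#' @param filter_window temporal moving-average window (samples) applied to
#'   the body potentials before inversion (see [smooth_body_potentials()];
#'   1 disables).
#' @param timing_smooth derivative smoothing window (samples) used when timing
#'   criteria are applied to reconstructed potentials (see
#'   [activation_time_temporal()]); ground-truth timings use unsmoothed
#'   derivatives.
#' @param seed master seed; all internal seeds are derived from it.
#' @return validated list of class `experiment_config`.
#' @export
experiment_config <- function(heart_radius = 40, torso_radius = 120,
                              n_heart_nodes = 812, n_torso_nodes = 1002,
                              n_electrodes = 200, conductivity = 0.2,
                              cell_model = "fhn", origins_per_region = 50L,
                              components = c(2L, 10L), n_test_beats = 5L,
                              test_regions = c("LV", "RV"), snr_db = 30,
                              dt = 1, n_steps = 550L,
                              target_spread = c(60, 100), folds = 5L,
                              n_eval_sites = 103L, filter_window = 5L,
                              timing_smooth = 9L, seed = 1L) {
  stopifnot(heart_radius > 0, torso_radius > heart_radius,
            length(components) == 2L, components[1] >= 1L,
            components[2] >= components[1],
            n_test_beats >= 1L, folds >= 2L)
  test_regions <- match.arg(test_regions, c("LV", "RV", "BASE_APEX"),
                            several.ok = TRUE)
  structure(list(heart_radius = heart_radius, torso_radius = torso_radius,
                 n_heart_nodes = n_heart_nodes, n_torso_nodes = n_torso_nodes,
                 n_electrodes = n_electrodes, conductivity = conductivity,
                 cell_model = cell_model,
                 origins_per_region = as.integer(origins_per_region),
                 components = as.integer(components),
                 n_test_beats = as.integer(n_test_beats),
                 test_regions = test_regions, snr_db = snr_db,
                 dt = dt, n_steps = as.integer(n_steps),
                 target_spread = target_spread, folds = as.integer(folds),
                 n_eval_sites = as.integer(n_eval_sites),
                 filter_window = as.integer(filter_window),
                 timing_smooth = as.integer(timing_smooth),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Epicardial evaluation sites (sock-electrode surrogate)
#'
#' Places `n_band` sites on four circumferential rows (two basal, two
#' mid-basal) and `n_apex` sites near the apex of a spherical epicardium,
#' mimicking a two-band epicardial sock plus apical electrodes.
#'
#' @param radius heart radius, mm.
#' @param n_band number of band sites (default 99).
#' @param n_apex number of apical sites (default 4).
#' @return matrix of 3D points (mm).
#' @export
epicardial_band_sites <- function(radius, n_band = 99L, n_apex = 4L) {
  rows <- c(55, 70, 95, 110) * pi / 180
  counts <- rep(n_band %/% 4L, 4L)
  counts[seq_len(n_band %% 4L)] <- counts[seq_len(n_band %% 4L)] + 1L
  pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    th <- rows[i]
    ph <- 2 * pi * (seq_len(counts[i]) - 1) / counts[i] + 0.1 * i
    cbind(radius * sin(th) * cos(ph), radius * sin(th) * sin(ph),
          radius * cos(th) * rep(1, counts[i]))
  }))
  tha <- 168 * pi / 180
  pha <- 2 * pi * (seq_len(n_apex) - 1) / n_apex
  rbind(pts, cbind(radius * sin(tha) * cos(pha), radius * sin(tha) * sin(pha),
                   radius * cos(tha) * rep(1, n_apex)))
}

#' Run the end-to-end synthetic benchmark
#'
#' Full pipeline: phantom geometry, BEM transfer matrix, coupling calibration,
#' simulated beats from pseudo-random origins in each region, SVD bases
#' (all-region and region-specific), held-out test beats forward-projected at
#' the configured SNR, Tikhonov (order 0, per-instant L-curve) and PBR
#' (per-instant cross-validated Lasso) reconstructions, activation/recovery
#' timing with both criteria, and electrode-matched statistics.
#'
#' The "recorded" electrograms are the ground-truth simulated potentials at
#' the evaluation sites' nearest heart nodes; recorded and reconstructed
#' traces are both re-referenced to zero spatial mean across those sites
#' before correlation, and timing criteria are applied with AP polarity
#' (the phantom's ground truth is action-potential shaped).
#'
#' @param config an [experiment_config()].
#' @param beat_count_sweep optional vector of basis beat counts: for each
#'   count `m`, a basis is rebuilt from the first `m` beats (in a seeded
#'   random order across regions) and the PBR reconstruction repeated.
#' @param component_sweep optional list of `c(first, last)` component ranges
#'   to re-evaluate with the all-region ensemble.
#' @param shuffle_electrodes destroy the electrode geometry by randomly
#'   permuting the rows of the body potentials (negative control).
#' @param verbose print per-stage progress.
#' @return object of class `ecgi_benchmark`; see `print` method. Key fields:
#'   `cc` (per site/beat/method), `cc_summary`, `timing`, `timing_pooled`,
#'   `localization`, `pvalues`, `sweep_beats`, `sweep_components`.
#' @export
run_benchmark <- function(config = experiment_config(), beat_count_sweep = NULL,
                          component_sweep = NULL, shuffle_electrodes = FALSE,
                          verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- proc.time()[3]
  stage <- function(lbl) say("[%6.1f s] %s", proc.time()[3] - t_start, lbl)
  seed <- config$seed

  stage("phantom geometry + BEM transfer matrix")
  geom <- generate_phantom(config$heart_radius, config$torso_radius,
                           config$n_heart_nodes, config$n_torso_nodes,
                           config$n_electrodes, config$conductivity,
                           seed = seed)
  tm <- compute_transfer_matrix(geom)
  heart <- geom$heart
  model <- cell_model(config$cell_model)
  labels <- label_regions(heart)

  stage("coupling calibration")
  gbar <- calibrate_gbar(heart, model, config$target_spread)

  regions <- c("LV", "RV", "BASE_APEX")
  basis_origins <- lapply(seq_along(regions), function(i)
    choose_beat_origins(labels, heart, regions[i], config$origins_per_region,
                        seed = seed + 10L + i))
  names(basis_origins) <- regions
  all_basis_origins <- unlist(basis_origins, use.names = FALSE)

  # held-out test origins: never a basis origin
  labels_free <- labels
  labels_free[all_basis_origins] <- NA
  per_region <- table(factor(rep(config$test_regions,
                                 length.out = config$n_test_beats),
                             levels = config$test_regions))
  test_origins <- integer(0); test_region <- character(0)
  for (r in names(per_region)) {
    if (per_region[[r]] == 0L) next
    o <- choose_beat_origins(labels_free, heart, r, per_region[[r]],
                             seed = seed + 20L + match(r, regions))
    test_origins <- c(test_origins, o)
    test_region <- c(test_region, rep(r, length(o)))
  }
  stopifnot(!any(test_origins %in% all_basis_origins))

  stage(sprintf("simulating %d basis beats (gbar = %.3g)",
                length(all_basis_origins), gbar))
  sim_one <- function(origin) simulate_beat(heart, model,
    propagation_params(gbar, dt = config$dt, n_steps = config$n_steps,
                       origin = origin))
  # round-robin over regions (seeded order within each region) so that any
  # prefix used by the beat-count sweep is region-balanced
  beat_region <- rep(regions, times = vapply(basis_origins, length, integer(1)))
  beat_order <- with_seed(seed + 30L, {
    by_region <- lapply(regions, function(r) sample(which(beat_region == r)))
    nmax <- max(lengths(by_region))
    ord <- unlist(lapply(seq_len(nmax), function(i)
      unlist(lapply(by_region, function(v) if (i <= length(v)) v[i]))))
    ord
  })
  grams <- vector("list", 3L)
  names(grams) <- regions
  gram_sweep <- NULL
  snapshots <- list()
  sweep_counts <- sort(unique(beat_count_sweep))
  for (b in seq_along(beat_order)) {
    i <- beat_order[b]
    beat <- sim_one(all_basis_origins[i])
    reg <- beat_region[i]
    grams[[reg]] <- gram_accumulate(grams[[reg]], beat$phi_H)
    gram_sweep <- gram_accumulate(gram_sweep, beat$phi_H)
    if (b %in% sweep_counts) snapshots[[as.character(b)]] <- gram_sweep
  }
  gram_all <- gram_sweep

  fb <- config$components[1]; lb <- config$components[2]
  stage("spatial bases (SVD)")
  basis_all <- basis_from_gram(gram_all, fb, lb)
  basis_region <- lapply(grams, basis_from_gram, first = fb, last = lb)

  stage(sprintf("simulating %d test beats + forward projection (SNR %g dB)",
                length(test_origins), config$snr_db))
  sites <- epicardial_band_sites(config$heart_radius,
                                 n_band = config$n_eval_sites - 4L, n_apex = 4L)
  site_nodes <- unique(match_electrodes_to_nodes(sites, heart))
  test_beats <- lapply(test_origins, sim_one)
  grad_op <- spatial_gradient_operator(heart)

  rereference_rows <- function(m) sweep(m, 2L, colMeans(m))
  cc_rows <- list(); timing_rows <- list(); loc_rows <- list()
  methods_per_beat <- c("tikhonov", "pbr_all", "pbr_spec")
  recon_store <- vector("list", length(test_beats))

  for (bi in seq_along(test_beats)) {
    stage(sprintf("test beat %d/%d (origin %d, %s)", bi, length(test_beats),
                  test_origins[bi], test_region[bi]))
    truth <- test_beats[[bi]]$phi_H
    bp <- forward_project(tm, truth, snr_db = config$snr_db,
                          seed = seed + 100L + bi, dt = config$dt)
    bp <- smooth_body_potentials(bp, config$filter_window)
    if (shuffle_electrodes) {
      perm <- with_seed(seed + 200L + bi, sample(nrow(bp$phi_B)))
      bp$phi_B <- bp$phi_B[perm, , drop = FALSE]
    }
    windows <- estimate_windows(truth, config$dt)
    truth_site <- rereference_rows(truth[site_nodes, , drop = FALSE])
    truth_maps <- list(
      temporal = compute_timing_map(truth, config$dt, windows, "temporal",
                                    polarity = "ap"),
      spatiotemporal = compute_timing_map(truth, config$dt, windows,
                                          "spatiotemporal", mesh = grad_op,
                                          polarity = "ap"))

    recons <- list(
      tikhonov = ecgi_reconstruct(bp, tm, "tikhonov", seed = seed),
      pbr_all = ecgi_reconstruct(bp, tm, "pbr", basis = basis_all,
                                 folds = config$folds, seed = seed),
      pbr_spec = ecgi_reconstruct(bp, tm, "pbr",
                                  basis = basis_region[[test_region[bi]]],
                                  folds = config$folds, seed = seed))
    recon_store[[bi]] <- recons

    for (mth in methods_per_beat) {
      rec <- recons[[mth]]$phi_H_hat
      rec_site <- rereference_rows(rec[site_nodes, , drop = FALSE])
      ccs <- vapply(seq_along(site_nodes), function(s)
        as.numeric(pearson_cc(truth_site[s, ], rec_site[s, ])), numeric(1))
      cc_rows[[length(cc_rows) + 1L]] <-
        data.frame(method = mth, beat = bi, node = site_nodes, cc = ccs)
      for (crit in c("temporal", "spatiotemporal")) {
        tmap <- compute_timing_map(rec, config$dt, windows, crit,
                                   mesh = grad_op, polarity = "ap",
                                   smooth_window = config$timing_smooth,
                                   interpolate = TRUE)
        tt <- truth_maps[[crit]]
        r_act <- tryCatch(as.numeric(timing_correlation(
          tt$tau_act_ms[site_nodes], tmap$tau_act_ms[site_nodes])),
          error = function(e) NA_real_)
        r_rec <- tryCatch(as.numeric(timing_correlation(
          tt$tau_rec_ms[site_nodes], tmap$tau_rec_ms[site_nodes])),
          error = function(e) NA_real_)
        timing_rows[[length(timing_rows) + 1L]] <-
          data.frame(method = mth, criterion = crit, beat = bi,
                     r_act = r_act, r_rec = r_rec)
        pred <- tryCatch(localize_origin(tmap), error = function(e) NA_integer_)
        loc_rows[[length(loc_rows) + 1L]] <-
          data.frame(method = mth, criterion = crit, beat = bi,
                     origin = test_origins[bi], pred = pred,
                     le_mm = if (is.na(pred)) NA_real_ else
                       localization_error(pred, test_origins[bi], heart))
      }
    }
  }

  cc <- do.call(rbind, cc_rows)
  timing <- do.call(rbind, timing_rows)
  localization <- do.call(rbind, loc_rows)
  cc_summary <- stats::aggregate(cc ~ method, cc,
                                 function(z) stats::median(z, na.rm = TRUE))

  # pooled timing correlations (all beats and sites of a method/criterion)
  pool <- function(mth, crit, field) {
    rec_v <- tru_v <- numeric(0)
    for (bi in seq_along(test_beats)) {
      tt <- compute_timing_map(test_beats[[bi]]$phi_H, config$dt,
                               estimate_windows(test_beats[[bi]]$phi_H, config$dt),
                               crit, mesh = grad_op, polarity = "ap")
      rc <- compute_timing_map(recon_store[[bi]][[mth]]$phi_H_hat, config$dt,
                               estimate_windows(test_beats[[bi]]$phi_H, config$dt),
                               crit, mesh = grad_op, polarity = "ap",
                               smooth_window = config$timing_smooth,
                               interpolate = TRUE)
      tru_v <- c(tru_v, tt[[field]][site_nodes])
      rec_v <- c(rec_v, rc[[field]][site_nodes])
    }
    tryCatch(as.numeric(timing_correlation(tru_v, rec_v)),
             error = function(e) NA_real_)
  }
  timing_pooled <- do.call(rbind, lapply(methods_per_beat, function(mth)
    do.call(rbind, lapply(c("temporal", "spatiotemporal"), function(crit)
      data.frame(method = mth, criterion = crit,
                 r_act = pool(mth, crit, "tau_act_ms"),
                 r_rec = pool(mth, crit, "tau_rec_ms"))))))

  paired_p <- function(m1, m2) {
    a <- cc$cc[cc$method == m1]
    b <- cc$cc[cc$method == m2]
    ok <- !is.na(a) & !is.na(b)
    wilcoxon_signed_rank(a[ok], b[ok])
  }
  pvalues <- data.frame(
    comparison = c("pbr_all vs tikhonov", "pbr_spec vs tikhonov"),
    p = c(paired_p("pbr_all", "tikhonov"), paired_p("pbr_spec", "tikhonov")))

  # ---- sweeps ---------------------------------------------------------------
  sweep_pbr <- function(basis) {
    ccs <- numeric(0)
    for (bi in seq_along(test_beats)) {
      truth <- test_beats[[bi]]$phi_H
      bp <- forward_project(tm, truth, snr_db = config$snr_db,
                            seed = seed + 100L + bi, dt = config$dt)
      bp <- smooth_body_potentials(bp, config$filter_window)
      rec <- ecgi_reconstruct(bp, tm, "pbr", basis = basis,
                              folds = config$folds, seed = seed)$phi_H_hat
      ts <- rereference_rows(truth[site_nodes, , drop = FALSE])
      rs <- rereference_rows(rec[site_nodes, , drop = FALSE])
      ccs <- c(ccs, vapply(seq_along(site_nodes), function(s)
        as.numeric(pearson_cc(ts[s, ], rs[s, ])), numeric(1)))
    }
    stats::median(ccs, na.rm = TRUE)
  }
  sweep_beats <- NULL
  if (length(sweep_counts)) {
    stage("beat-count sweep")
    sweep_beats <- do.call(rbind, lapply(sweep_counts, function(m) {
      g <- snapshots[[as.character(m)]]
      eg <- eigen(g, symmetric = TRUE)
      d <- sqrt(pmax(eg$values, 0))
      rank_g <- sum(d > 1e-10 * d[1])
      lb_m <- min(lb, rank_g)
      bas_m <- truncate_basis(list(u = fix_svd_signs(eg$vectors), d = d),
                              first = min(fb, lb_m), last = lb_m)
      data.frame(n_beats = m, median_cc = sweep_pbr(bas_m))
    }))
  }
  sweep_components <- NULL
  if (length(component_sweep)) {
    stage("component-range sweep")
    sweep_components <- do.call(rbind, lapply(component_sweep, function(rg)
      data.frame(first = rg[1], last = rg[2], k = rg[2] - rg[1] + 1,
                 median_cc = sweep_pbr(basis_from_gram(gram_all, rg[1], rg[2])))))
  }

  stage("done")
  structure(list(cc = cc, cc_summary = cc_summary, timing = timing,
                 timing_pooled = timing_pooled, localization = localization,
                 pvalues = pvalues, sweep_beats = sweep_beats,
                 sweep_components = sweep_components,
                 gbar = as.numeric(gbar), config = config,
                 site_nodes = site_nodes, test_origins = test_origins,
                 test_region = test_region,
                 basis_singular_values = basis_all$d,
                 elapsed_s = proc.time()[3] - t_start),
            class = "ecgi_benchmark")
}

#' @export
print.ecgi_benchmark <- function(x, ...) {
  cat("Synthetic ECGI benchmark\n")
  cat(sprintf("  %d test beats, %d evaluation sites, SNR %g dB, %d origins/region\n",
              length(x$test_origins), length(x$site_nodes), x$config$snr_db,
              x$config$origins_per_region))
  cat("  median electrogram CC by method:\n")
  for (i in seq_len(nrow(x$cc_summary)))
    cat(sprintf("    %-9s %.3f\n", x$cc_summary$method[i], x$cc_summary$cc[i]))
  le <- x$localization
  le_med <- stats::aggregate(le_mm ~ method + criterion, le,
                             function(z) stats::median(z, na.rm = TRUE))
  cat("  median localization error (mm):\n")
  for (i in seq_len(nrow(le_med)))
    cat(sprintf("    %-9s %-14s %.1f\n", le_med$method[i], le_med$criterion[i],
                le_med$le_mm[i]))
  cat("  paired Wilcoxon p-values:\n")
  for (i in seq_len(nrow(x$pvalues)))
    cat(sprintf("    %-22s %.2g\n", x$pvalues$comparison[i], x$pvalues$p[i]))
  if (!is.null(x$sweep_beats)) {
    cat("  beat-count sweep (median CC):\n")
    for (i in seq_len(nrow(x$sweep_beats)))
      cat(sprintf("    %2d beats: %.3f\n", x$sweep_beats$n_beats[i],
                  x$sweep_beats$median_cc[i]))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
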