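#' Save and load the artifacts of an inverse-reconstruction run
#'
#' Plain-text run container: a directory with one subdirectory per artifact
#' group, mirroring the logical layout `transfer/A`, `geometry/electrodes`,
#' `sim/beats/<i>`, `basis/U_k`, `inverse/<method>/phi_H_hat`, `timing/`.
#' Matrices are headerless CSV; scalar metadata is JSON (written without
#' external dependencies); meshes are ASCII PLY.
#'
#' @param dir container directory (created if missing).
#' @param geometry optional [generate_phantom()] result.
#' @param transfer optional [compute_transfer_matrix()] result.
#' @param beats optional list of [simulate_beat()] results.
#' @param basis optional [truncate_basis()] result.
#' @param recon optional named list of [ecgi_reconstruct()] fits.
#' @param timing optional named list of [compute_timing_map()] results.
#' @return `dir`, invisibly.
#' @export
ecgi_save_run <- function(dir, geometry = NULL, transfer = NULL, beats = NULL,
                          basis = NULL, recon = NULL, timing = NULL) {
  mk <- function(...) {
    p <- file.path(dir, ...)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    p
  }
  if (!is.null(geometry)) {
    write_ply(geometry$heart, mk("geometry", "heart.ply"))
    write_ply(geometry$torso, mk("geometry", "torso.ply"))
    write_matrix_csv(geometry$electrodes, mk("geometry", "electrodes.csv"))
    write_json_min(list(conductivity_S_per_m = geometry$conductivity),
                   mk("geometry", "meta.json"))
  }
  if (!is.null(transfer)) {
    write_matrix_csv(transfer$A, mk("transfer", "A.csv"))
    write_matrix_csv(matrix(transfer$electrode_nodes, ncol = 1),
                     mk("transfer", "electrode_nodes.csv"))
  }
  if (!is.null(beats)) {
    for (i in seq_along(beats)) {
      b <- beats[[i]]
      write_matrix_csv(b$phi_H, mk("sim", "beats", sprintf("beat_%03d.csv", i)))
      write_json_min(list(origin = b$origin, model = b$model, dt_ms = b$dt),
                     mk("sim", "beats", sprintf("beat_%03d.json", i)))
    }
  }
  if (!is.null(basis)) {
    write_matrix_csv(basis$U_k, mk("basis", "U_k.csv"))
    write_matrix_csv(matrix(basis$d, ncol = 1), mk("basis", "singular_values.csv"))
    write_json_min(list(first = basis$range[[1]], last = basis$range[[2]]),
                   mk("basis", "component_range.json"))
  }
  if (!is.null(recon)) {
    for (nm in names(recon)) {
      r <- recon[[nm]]
      write_matrix_csv(r$phi_H_hat, mk("inverse", nm, "phi_H_hat.csv"))
      write_matrix_csv(matrix(r$lambda_t, ncol = 1), mk("inverse", nm, "lambda_t.csv"))
      if (!is.null(r$beta_t))
        write_matrix_csv(r$beta_t, mk("inverse", nm, "beta_t.csv"))
    }
  }
  if (!is.null(timing)) {
    for (nm in names(timing)) {
      utils::write.csv(as.data.frame(timing[[nm]]),
                       mk("timing", paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname ecgi_save_run
#' @param what artifact group to load: `"transfer"`, `"basis"`,
#'   `"geometry"`, `"beats"`, `"inverse"` or `"timing"`.
#' @param name method / map name for `"inverse"` and `"timing"`.
#' @export
ecgi_load_run <- function(dir, what, name = NULL) {
  switch(what,
    transfer = list(A = read_matrix_csv(file.path(dir, "transfer", "A.csv")),
                    electrode_nodes = as.integer(
                      read_matrix_csv(file.path(dir, "transfer", "electrode_nodes.csv")))),
    basis = {
      rng <- read_json_min(file.path(dir, "basis", "component_range.json"))
      structure(list(U_k = read_matrix_csv(file.path(dir, "basis", "U_k.csv")),
                     d = as.numeric(read_matrix_csv(
                       file.path(dir, "basis", "singular_values.csv"))),
                     range = c(first = rng$first, last = rng$last)),
                class = "spatial_basis")
    },
    geometry = list(heart = read_ply(file.path(dir, "geometry", "heart.ply")),
                    torso = read_ply(file.path(dir, "geometry", "torso.ply")),
                    electrodes = read_matrix_csv(file.path(dir, "geometry", "electrodes.csv"))),
    beats = {
      files <- sort(list.files(file.path(dir, "sim", "beats"),
                               pattern = "^beat_\\d+\\.csv$", full.names = TRUE))
      lapply(files, function(f) {
        meta <- read_json_min(sub("\\.csv$", ".json", f))
        structure(list(phi_H = read_matrix_csv(f), origin = as.integer(meta$origin),
                       model = meta$model, dt = meta$dt_ms),
                  class = "simulated_beat")
      })
    },
    inverse = list(phi_H_hat = read_matrix_csv(file.path(dir, "inverse", name, "phi_H_hat.csv")),
                   lambda_t = as.numeric(read_matrix_csv(
                     file.path(dir, "inverse", name, "lambda_t.csv")))),
    timing = utils::read.csv(file.path(dir, "timing", paste0(name, ".csv"))),
    stop("unknown artifact group: ", what))
}

# minimal flat JSON writer/reader (scalar fields only), keeps the run
# container dependency-free
write_json_min <- function(x, path) {
  fmt <- vapply(x, function(v) {
    if (is.character(v)) paste0('"', v, '"') else format(v, digits = 17)
  }, character(1))
  writeLines(paste0("{", paste(sprintf('"%s": %s', names(x), fmt), collapse = ", "),
                    "}"), path)
  invisible(path)
}

read_json_min <- function(path) {
  s <- paste(readLines(path, warn = FALSE), collapse = " ")
  s <- sub("^\\s*\\{", "", sub("\\}\\s*$", "", s))
  parts <- strsplit(s, ",(?=\\s*\")", perl = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    key <- gsub('^\\s*"|"\\s*$', "", kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    out[[key]] <- if (grepl('^"', val)) gsub('^"|"$', "", val) else as.numeric(val)
  }
  out
}
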