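#' Read and write meshes in ASCII PLY and OFF formats
#'
#' Minimal readers/writers for the two classic polygon formats, restricted to
#' triangle meshes. Vertex indices are 0-based inside the files (as both
#' formats require) and 1-based in R.
#'
#' @param mesh a [tri_mesh()].
#' @param path file path.
#' @return `read_ply`/`read_off` return a [tri_mesh()]; the writers return
#'   `path` invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1L, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1L, function(r) paste(c(3L, r - 1L), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "ply") stop("not a PLY file")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  body <- lines[(hdr_end + 1L):length(lines)]
  vals <- lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric)
  v <- do.call(rbind, vals)[, 1:3, drop = FALSE]
  fvals <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), as.integer)
  f <- do.call(rbind, fvals)
  if (any(f[, 1] != 3L)) stop("only triangle PLY faces are supported")
  tri_mesh(v, f[, 2:4, drop = FALSE] + 1L)
}

#' @rdname write_ply
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$faces), 0L), con)
  writeLines(apply(mesh$vertices, 1L, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1L, function(r) paste(c(3L, r - 1L), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vals <- lapply(strsplit(trimws(lines[2 + seq_len(nv)]), "\\s+"), as.numeric)
  v <- do.call(rbind, vals)[, 1:3, drop = FALSE]
  fvals <- lapply(strsplit(trimws(lines[2 + nv + seq_len(nf)]), "\\s+"), as.integer)
  f <- do.call(rbind, fvals)
  if (any(f[, 1] != 3L)) stop("only triangle OFF faces are supported")
  tri_mesh(v, f[, 2:4, drop = FALSE] + 1L)
}

#' Write a matrix as headerless CSV
#'
#' Plain-text exchange format used by the run container for matrices such as
#' the transfer matrix or potential series.
#'
#' @param x numeric matrix.
#' @param path file path.
#' @export
write_matrix_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
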