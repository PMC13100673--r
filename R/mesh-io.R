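# ASCII mesh I/O (PLY and OFF), coordinates in mm. Element labels travel
# in a sidecar CSV (element_id, label) since neither format carries
# per-face strings portably.

#' Write a mesh as ASCII PLY
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path input file path.
#' @param labels optional path to a label sidecar CSV (see
#'   [write_mesh_labels()]).
#' @return a [surface_mesh()].
#' @export
read_ply <- function(path, labels = NULL) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("not an ASCII PLY file")
  hdr_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vtx <- matrix(scan(text = lines[hdr_end + seq_len(nv)], quiet = TRUE),
                nv, 3, byrow = TRUE)
  face_rows <- lines[hdr_end + nv + seq_len(nf)]
  f <- matrix(scan(text = face_rows, quiet = TRUE), nf, 4, byrow = TRUE)
  if (any(f[, 1] != 3)) stop("only triangular faces are supported")
  tri <- f[, 2:4, drop = FALSE] + 1L
  lab <- if (!is.null(labels)) read_mesh_labels(labels, nf) else NULL
  surface_mesh(vtx, tri, lab)
}

#' Write a mesh as ASCII OFF
#' @inheritParams write_ply
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF",
               paste(nrow(mesh$vertices), nrow(mesh$triangles), 0)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Read an ASCII OFF mesh
#' @inheritParams read_ply
#' @return a [surface_mesh()].
#' @export
read_off <- function(path, labels = NULL) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]
  nf <- counts[2]
  vtx <- matrix(scan(text = lines[2 + seq_len(nv)], quiet = TRUE),
                nv, 3, byrow = TRUE)
  f <- matrix(scan(text = lines[2 + nv + seq_len(nf)], quiet = TRUE),
              nf, 4, byrow = TRUE)
  if (any(f[, 1] != 3)) stop("only triangular faces are supported")
  lab <- if (!is.null(labels)) read_mesh_labels(labels, nf) else NULL
  surface_mesh(vtx, f[, 2:4, drop = FALSE] + 1L, lab)
}

#' Write per-element labels as a sidecar CSV
#' @param mesh a [surface_mesh()] with labels.
#' @param path output CSV path (`element_id,label`).
#' @export
write_mesh_labels <- function(mesh, path) {
  if (is.null(mesh$labels)) stop("mesh has no labels")
  write.csv(data.frame(element_id = seq_len(n_elements(mesh)),
                       label = mesh$labels),
            path, row.names = FALSE)
  invisible(path)
}

read_mesh_labels <- function(path, n) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lab <- rep(NA_character_, n)
  lab[df$element_id] <- df$label
  lab
}
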