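#' Triangle mesh object
#'
#' A shared-vertex triangle mesh used for muscle and bone surfaces.  Vertices
#' are stored in metres; face indices are 1-based (converted from the 0-based
#' conventions of on-disk formats at load time).
#'
#' @param vertices numeric matrix, one 3D point per row (metres).
#' @param faces integer matrix, one triangle per row, 1-based vertex indices.
#' @param name identifier carried through the pipeline.
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stopf("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stopf("faces must be an m x 3 matrix")
  if (nrow(vertices) == 0L || nrow(faces) == 0L) stopf("mesh '%s' is empty", name)
  if (any(!is.finite(vertices))) stopf("mesh '%s' has non-finite vertices", name)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stopf("mesh '%s': face indices out of range [1, %d]", name, nrow(vertices))
  }
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

# All edges, one row per face-edge occurrence (unsorted endpoints).
face_edges <- function(faces) {
  rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
}

# Undirected edge keys ("lo-hi") per face-edge occurrence.
edge_keys <- function(edges) {
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  paste(lo, hi, sep = "-")
}

# Per-face doubled area vectors (cross products) and areas.
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

face_areas <- function(mesh) 0.5 * row_norms(face_normals(mesh))

face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
     v[f[, 3L], , drop = FALSE]) / 3
}

#' Euler characteristic of a mesh
#'
#' V - E + F; equals 2 for a watertight sphere-topology surface and 1 for a
#' topological disk.
#'
#' @param mesh a [trimesh()].
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  e <- length(unique(edge_keys(face_edges(mesh$faces))))
  n_vertices(mesh) - e + n_faces(mesh)
}
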