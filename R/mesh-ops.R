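# Mesh cleaning, smoothing, boundary extraction and sphere fitting.

#' Clean a triangle mesh
#'
#' Welds vertices closer than `weld_tol`, removes degenerate (repeated-index
#' or zero-area) faces, and removes faces incident to non-manifold edges
#' (edges shared by more than two faces).  Unreferenced vertices are dropped.
#' The operation is idempotent.
#'
#' @param mesh a [trimesh()].
#' @param weld_tol welding tolerance in metres.  The default (1e-6 m) is
#'   below typical medical-imaging resolution but above float round-off.
#' @return a cleaned [trimesh()].
#' @export
clean_mesh <- function(mesh, weld_tol = 1e-6) {
  v <- mesh$vertices
  f <- mesh$faces
  welded <- weld_soup(v, tol = weld_tol)
  map <- welded$index
  v <- welded$vertices
  f <- matrix(map[f], ncol = 3L)

  # degenerate faces: repeated indices or (numerically) zero area
  repeated <- f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]
  f <- f[!repeated, , drop = FALSE]
  if (nrow(f) > 0L) {
    areas <- face_areas(list(vertices = v, faces = f))
    f <- f[areas > 1e-18, , drop = FALSE]
  }

  # faces touching edges shared by more than two faces
  if (nrow(f) > 0L) {
    keys <- edge_keys(face_edges(f))
    counts <- table(keys)
    bad <- names(counts)[counts > 2L]
    if (length(bad)) {
      occ <- matrix(keys %in% bad, ncol = 3L)
      f <- f[!apply(occ, 1L, any), , drop = FALSE]
    }
  }
  if (nrow(f) == 0L) stopf("cleaning mesh '%s' removed every face", mesh$name)

  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  trimesh(v[used, , drop = FALSE], matrix(remap[f], ncol = 3L),
          name = mesh$name)
}

#' Smooth a triangle mesh (Taubin lambda/mu)
#'
#' Each iteration applies an umbrella-weight Laplacian shrink step with factor
#' `factor` followed by an inflate step with factor `-(factor + 0.03)`,
#' limiting the volume shrinkage of plain Laplacian smoothing.  Boundary
#' vertices are held fixed; connectivity is unchanged.
#'
#' @param mesh a [trimesh()].
#' @param iterations number of shrink/inflate pairs (>= 0).
#' @param factor positive smoothing factor in (0, 1); 0.5 by default.
#' @return the smoothed [trimesh()].
#' @export
smooth_mesh <- function(mesh, iterations, factor = 0.5) {
  if (iterations < 0) stopf("iterations must be >= 0")
  if (factor <= 0 || factor >= 1) stopf("smoothing factor must be in (0, 1)")
  if (iterations == 0) return(mesh)

  edges <- unique_edges(mesh$faces)
  counts <- edge_face_counts(mesh$faces)
  boundary_v <- unique(as.vector(counts$edges[counts$count == 1L, ]))
  free <- setdiff(seq_len(n_vertices(mesh)), boundary_v)

  v <- mesh$vertices
  nv <- nrow(v)
  i <- c(edges[, 1L], edges[, 2L])
  j <- c(edges[, 2L], edges[, 1L])
  adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(adj)
  deg[deg == 0] <- 1

  laplace_step <- function(v, s) {
    avg <- as.matrix(adj %*% v) / deg
    v[free, ] <- v[free, ] + s * (avg[free, , drop = FALSE] -
                                    v[free, , drop = FALSE])
    v
  }
  mu <- -(factor + 0.03)
  for (it in seq_len(iterations)) {
    v <- laplace_step(v, factor)
    v <- laplace_step(v, mu)
  }
  out <- mesh
  out$vertices <- v
  out
}

unique_edges <- function(faces) {
  e <- face_edges(faces)
  lo <- pmin(e[, 1L], e[, 2L])
  hi <- pmax(e[, 1L], e[, 2L])
  unique(cbind(lo, hi))
}

# Undirected edges with their incident-face counts.
edge_face_counts <- function(faces) {
  e <- face_edges(faces)
  lo <- pmin(e[, 1L], e[, 2L])
  hi <- pmax(e[, 1L], e[, 2L])
  key <- paste(lo, hi, sep = "-")
  tab <- table(key)
  first <- !duplicated(key)
  ord <- match(names(tab), key[first])
  list(edges = cbind(lo[first], hi[first])[ord, , drop = FALSE],
       count = as.integer(tab))
}

#' Extract ordered boundary loops
#'
#' Finds all edges incident to exactly one face and chains them into closed,
#' ordered loops (one per connected boundary component).  A closed mesh
#' yields an empty list.
#'
#' @param mesh an edge-manifold [trimesh()].
#' @return a list of integer vectors of class `boundary_loop`, each an
#'   ordered cyclic sequence of vertex indices.
#' @export
boundary_loops <- function(mesh) {
  counts <- edge_face_counts(mesh$faces)
  if (any(counts$count > 2L)) {
    stopf("mesh '%s' has non-manifold edges; clean_mesh() first", mesh$name)
  }
  be <- counts$edges[counts$count == 1L, , drop = FALSE]
  if (nrow(be) == 0L) return(list())

  # adjacency: each boundary vertex appears in exactly 2 boundary edges
  nbr <- split(c(be[, 2L], be[, 1L]), c(be[, 1L], be[, 2L]))
  if (any(lengths(nbr) != 2L)) {
    stopf("mesh '%s' has a non-manifold boundary vertex", mesh$name)
  }
  visited <- new.env(hash = TRUE)
  loops <- list()
  for (start in as.integer(names(nbr))) {
    skey <- as.character(start)
    if (!is.null(visited[[skey]])) next
    loop <- integer(0)
    prev <- NA_integer_
    cur <- start
    repeat {
      loop <- c(loop, cur)
      visited[[as.character(cur)]] <- TRUE
      nxt <- nbr[[as.character(cur)]]
      nxt <- nxt[is.na(prev) | nxt != prev]
      prev <- cur
      cur <- nxt[1L]
      if (cur == start) break
    }
    loops[[length(loops) + 1L]] <- structure(loop, class = "boundary_loop")
  }
  loops
}

#' Least-squares sphere fit
#'
#' Algebraic (linearised) least squares: solving
#' `2 c . p + k = |p|^2` for the centre `c` and `k = r^2 - |c|^2`.  Exact to
#' machine precision on noiseless spherical data and deterministic.
#'
#' @param points numeric matrix of 3D points, at least 4 and not coplanar.
#' @return a list with `center` (3-vector, m) and `radius` (m), class
#'   `sphere`.
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stopf("fit_sphere needs at least 4 points")
  # work in a centred frame for conditioning
  mu <- colMeans(points)
  q <- sweep(points, 2L, mu)
  A <- cbind(2 * q, 1)
  b <- rowSums(q^2)
  sv <- svd(A)
  if (sv$d[4L] < 1e-10 * sv$d[1L]) {
    stopf("fit_sphere: points are coplanar or otherwise degenerate")
  }
  x <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
  center <- as.vector(x[1:3]) + mu
  radius <- sqrt(x[4L] + sum(x[1:3]^2))
  if (!is.finite(radius) || radius <= 0) {
    stopf("fit_sphere: degenerate radius")
  }
  structure(list(center = center, radius = radius), class = "sphere")
}
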