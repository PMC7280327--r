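# Harmonic scalar field between the two attachment boundaries.
#
# The field orders the muscle cross-sections from origin (value 0) to
# insertion (value 1).  It is the discrete harmonic interpolant for the
# cotangent-weight Laplacian, with negative cotangent weights clamped to
# zero so the discrete maximum principle holds on imperfect meshes.

#' Solve the origin-to-insertion scalar field
#'
#' Discrete harmonic (Laplace) interpolation with Dirichlet boundary values:
#' 0 on the origin boundary loop and 1 on the insertion loop.  The sparse
#' symmetric positive-definite system is solved with a Cholesky factorisation.
#'
#' @param mesh an open [trimesh()] whose only boundary loops are the two
#'   given ones.
#' @param origin_loop,insertion_loop [boundary_loops()] entries holding the
#'   attachment boundaries.
#' @return a list of class `field_on_mesh` with elements `mesh` and
#'   `values` (one scalar in \[0, 1\] per vertex).
#' @export
solve_field <- function(mesh, origin_loop, insertion_loop) {
  loops <- boundary_loops(mesh)
  if (length(loops) != 2L) {
    stopf("solve_field: mesh has %d boundary loops, expected exactly 2",
          length(loops))
  }
  all_loop_v <- sort(unlist(loops))
  given <- sort(c(as.integer(origin_loop), as.integer(insertion_loop)))
  if (!identical(all_loop_v, given)) {
    stopf("solve_field: given loops do not match the mesh boundary")
  }

  nv <- n_vertices(mesh)
  W <- cotan_weight_matrix(mesh)
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W

  bnd <- c(as.integer(origin_loop), as.integer(insertion_loop))
  ub <- c(rep(0, length(origin_loop)), rep(1, length(insertion_loop)))
  interior <- setdiff(seq_len(nv), bnd)

  values <- numeric(nv)
  values[bnd] <- ub
  if (length(interior)) {
    Lii <- L[interior, interior, drop = FALSE]
    rhs <- -L[interior, bnd, drop = FALSE] %*% ub
    ui <- tryCatch(
      as.vector(Matrix::solve(Lii, rhs)),
      error = function(e) stopf("solve_field: singular system (%s)",
                                conditionMessage(e)))
    res <- max(abs(Lii %*% ui - rhs))
    if (!is.finite(res) || res > 1e-8 * max(1, max(abs(ui)))) {
      stopf("solve_field: solver residual too large (%g)", res)
    }
    values[interior] <- pmin(1, pmax(0, ui))
  }
  structure(list(mesh = mesh, values = values), class = "field_on_mesh")
}

# Symmetric cotangent edge-weight matrix with negative weights clamped to 0.
cotan_weight_matrix <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  corners <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  for (c0 in corners) {
    a <- f[, c0[1L]]; b <- f[, c0[2L]]; d <- f[, c0[3L]]
    # cotangent of the angle at vertex a, opposite the edge (b, d)
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[d, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(u * w)
    crs <- row_norms(cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
                           u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
                           u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L]))
    crs[crs < 1e-300] <- 1e-300
    cot <- dot / crs
    ii <- c(ii, b, d)
    jj <- c(jj, d, b)
    xx <- c(xx, 0.5 * cot, 0.5 * cot)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
  W@x <- pmax(W@x, 0)  # clamp for the maximum principle
  Matrix::drop0(W)
}

#' Extract a closed isoline of the field
#'
#' Marching-triangles extraction: each triangle whose vertex values bracket
#' `level` contributes one segment between the linearly interpolated edge
#' crossings; segments are chained into closed loops.  When several loops
#' exist the largest-perimeter one is kept (with a warning).  Orientation is
#' normalised counter-clockwise about the mean field-gradient direction.
#' Vertices whose value equals `level` exactly are perturbed by 1e-12 first.
#'
#' @param field a `field_on_mesh` from [solve_field()].
#' @param level isoline value, strictly between 0 and 1.
#' @return a list of class `closed_contour` with `points` (ordered cyclic
#'   n x 3 matrix), `level` and `winding` (+1 once normalised).
#' @export
extract_isoline <- function(field, level) {
  if (level <= 0 || level >= 1) stopf("isoline level must be in (0, 1)")
  mesh <- field$mesh
  vals <- field$values
  vals[vals == level] <- level + 1e-12

  v <- mesh$vertices
  f <- mesh$faces
  segs <- isoline_segments(v, f, vals, level)
  if (length(segs$loops) == 0L) {
    stopf("no closed isoline found at level %g", level)
  }
  loops <- segs$loops
  perims <- vapply(loops, function(p) {
    sum(row_norms(p[c(2:nrow(p), 1L), , drop = FALSE] - p))
  }, 0)
  if (length(loops) > 1L) {
    warning(sprintf("isoline level %g has %d loops; keeping the largest",
                    level, length(loops)), call. = FALSE)
  }
  pts <- loops[[which.max(perims)]]

  # orient CCW about the mean field gradient
  g <- mean_field_gradient(mesh, vals)
  nrm <- newell_normal(pts)
  winding <- 1L
  if (sum(nrm * g) < 0) {
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  }
  structure(list(points = pts, level = level, winding = winding),
            class = "closed_contour")
}

# Chain per-triangle crossing segments into closed loops of 3D points.
isoline_segments <- function(v, f, vals, level) {
  s <- vals - level
  sv <- matrix(s[f], ncol = 3L)
  # edges within each face, as column pairs
  epairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  cross <- sapply(epairs, function(e) sv[, e[1L]] * sv[, e[2L]] < 0)
  if (is.null(dim(cross))) cross <- matrix(cross, ncol = 3L)
  nf <- nrow(f)
  hit <- which(rowSums(cross) == 2L)
  if (length(hit) == 0L) return(list(loops = list()))

  # crossing point and undirected-edge key for each (face, edge) crossing
  seg_from <- character(0); seg_to <- character(0)
  pt_env <- new.env(hash = TRUE)
  for (fi in hit) {
    keys2 <- character(0)
    for (k in 1:3) {
      if (!cross[fi, k]) next
      e <- epairs[[k]]
      i1 <- f[fi, e[1L]]; i2 <- f[fi, e[2L]]
      t <- s[i1] / (s[i1] - s[i2])
      p <- (1 - t) * v[i1, ] + t * v[i2, ]
      key <- paste(min(i1, i2), max(i1, i2), sep = "-")
      if (is.null(pt_env[[key]])) pt_env[[key]] <- p
      keys2 <- c(keys2, key)
    }
    seg_from <- c(seg_from, keys2[1L])
    seg_to <- c(seg_to, keys2[2L])
  }

  # adjacency between crossed edges; closed loops have degree 2 everywhere
  nbr <- split(c(seg_to, seg_from), c(seg_from, seg_to))
  loops <- list()
  visited <- new.env(hash = TRUE)
  for (start in names(nbr)) {
    if (!is.null(visited[[start]])) next
    if (length(nbr[[start]]) != 2L) {  # open chain (touches boundary): skip
      visited[[start]] <- TRUE
      next
    }
    chain <- character(0)
    prev <- NA_character_
    cur <- start
    ok <- TRUE
    repeat {
      chain <- c(chain, cur)
      visited[[cur]] <- TRUE
      nxt <- nbr[[cur]]
      if (length(nxt) != 2L) { ok <- FALSE; break }
      nxt <- if (is.na(prev)) nxt[1L] else nxt[nxt != prev][1L]
      if (is.na(nxt)) { ok <- FALSE; break }
      prev <- cur
      cur <- nxt
      if (cur == start) break
    }
    if (ok && length(chain) >= 3L) {
      pts <- do.call(rbind, lapply(chain, function(k) pt_env[[k]]))
      loops[[length(loops) + 1L]] <- pts
    }
  }
  list(loops = loops)
}

# Area-weighted mean of per-face gradients of a piece-wise linear field.
mean_field_gradient <- function(mesh, vals) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- face_normals(mesh)         # doubled-area vectors
  a2 <- row_norms(nrm)
  a2[a2 < 1e-300] <- 1e-300
  unit_n <- nrm / a2
  g <- matrix(0, nrow(f), 3L)
  idx <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  for (k in idx) {
    vi <- f[, k[1L]]
    e <- v[f[, k[3L]], , drop = FALSE] - v[f[, k[2L]], , drop = FALSE]
    rot <- cbind(unit_n[, 2L] * e[, 3L] - unit_n[, 3L] * e[, 2L],
                 unit_n[, 3L] * e[, 1L] - unit_n[, 1L] * e[, 3L],
                 unit_n[, 1L] * e[, 2L] - unit_n[, 2L] * e[, 1L])
    g <- g + vals[vi] * rot
  }
  g <- g / a2
  total <- colSums(g * (a2 / 2))
  normalize(total)
}

# Newell polygon normal (area vector) of a closed 3D polygon.
newell_normal <- function(pts) {
  nxt <- pts[c(2:nrow(pts), 1L), , drop = FALSE]
  c(sum((pts[, 2L] - nxt[, 2L]) * (pts[, 3L] + nxt[, 3L])),
    sum((pts[, 3L] - nxt[, 3L]) * (pts[, 1L] + nxt[, 1L])),
    sum((pts[, 1L] - nxt[, 1L]) * (pts[, 2L] + nxt[, 2L])))
}

#' Extract an ordered, resampled stack of isolines
#'
#' Extracts `n_points` contours at levels `k / (n_points + 1)`,
#' `k = 1..n_points`, ordered origin to insertion.  Each contour is resampled
#' to `n_samples` arc-length-uniform points and the cyclic correspondence is
#' propagated between consecutive contours by nearest-point alignment, which
#' prevents twist in the mapped fibre architecture.  The first contour is
#' anchored at the sample of minimum angular coordinate about the
#' origin-to-insertion axis.
#'
#' @param field a `field_on_mesh`.
#' @param n_points number of contours (>= 2).
#' @param n_samples resampling count per contour (default 64).
#' @return list of `closed_contour`, each with `n_samples` points.
#' @export
contour_stack <- function(field, n_points, n_samples = 64L) {
  if (n_points < 2L) stopf("contour_stack needs n_points >= 2")
  levels <- seq_len(n_points) / (n_points + 1)
  contours <- vector("list", n_points)
  for (k in seq_len(n_points)) {
    contours[[k]] <- tryCatch(
      extract_isoline(field, levels[k]),
      error = function(e) stopf("contour extraction failed at level %g: %s",
                                levels[k], conditionMessage(e)))
    contours[[k]]$points <- resample_closed(contours[[k]]$points, n_samples)
  }

  # anchor the first contour about the attachment-centroid axis
  c0 <- colMeans(field$mesh$vertices[field$values <= 1e-9, , drop = FALSE])
  c1 <- colMeans(field$mesh$vertices[field$values >= 1 - 1e-9, , drop = FALSE])
  axis <- normalize(c1 - c0)
  e1 <- perp_vector(axis)
  e2 <- cross3(axis, e1)
  p <- contours[[1L]]$points
  rel <- sweep(p, 2L, colMeans(p))
  ang <- atan2(rel %*% e2, rel %*% e1) %% (2 * pi)
  shift <- which.min(ang)
  contours[[1L]]$points <- cyclic_shift(p, shift)

  for (k in seq_len(n_points)[-1L]) {
    contours[[k]]$points <- align_cyclic(contours[[k]]$points,
                                         contours[[k - 1L]]$points)
  }
  contours
}

# Resample a closed 3D polyline to n arc-length-uniform points.
resample_closed <- function(pts, n) {
  # drop coincident consecutive points (zero-length segments)
  m0 <- nrow(pts)
  keep <- c(TRUE, row_norms(pts[-1L, , drop = FALSE] -
                              pts[-m0, , drop = FALSE]) > 1e-14)
  pts <- pts[keep, , drop = FALSE]
  m <- nrow(pts)
  closed <- rbind(pts, pts[1L, , drop = FALSE])
  seglen <- row_norms(closed[-1L, , drop = FALSE] - closed[-(m + 1L), , drop = FALSE])
  s <- c(0, cumsum(seglen))
  total <- s[m + 1L]
  target <- (seq_len(n) - 1L) / n * total
  out <- matrix(0, n, 3L)
  for (j in 1:3) {
    out[, j] <- stats::approx(s, closed[, j], xout = target, rule = 2)$y
  }
  out
}

cyclic_shift <- function(pts, start) {
  n <- nrow(pts)
  pts[((seq_len(n) + start - 2L) %% n) + 1L, , drop = FALSE]
}

# Best cyclic shift (and possible reversal) of pts minimising total distance
# to the same-index points of ref.
align_cyclic <- function(pts, ref) {
  n <- nrow(pts)
  best <- NULL
  best_cost <- Inf
  for (dir in list(pts, pts[rev(seq_len(n)), , drop = FALSE])) {
    # cost of shift s = sum_i |dir[(i+s-1) mod n + 1] - ref[i]|
    for (s in 0:(n - 1L)) {
      idx <- ((seq_len(n) + s - 1L) %% n) + 1L
      cost <- sum(row_norms(dir[idx, , drop = FALSE] - ref))
      if (cost < best_cost) {
        best_cost <- cost
        best <- dir[idx, , drop = FALSE]
      }
    }
  }
  best
}
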