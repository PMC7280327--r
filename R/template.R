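# Fibre-architecture templates in the unit cube and their barycentric
# transfer onto mesh contours.
#
# A template describes the internal fibre arrangement of a muscle in a
# normalised unit space: fibres run from the origin face (z = 0) to the
# insertion face (z = 1) as Bezier curves.  Slicing the template with planes
# z = level gives per-level 2D fibre points, which are expressed relative to
# the template's boundary polygon through mean-value coordinates and mapped
# onto the corresponding mesh contour by the same weights.

#' Parallel-fibre template
#'
#' Vertical straight fibres (degenerate Bezier curves) seeded on a
#' `ceiling(sqrt(n))`-square uniform interior grid, truncated row-major to
#' `n_fibers`.  For 100 fibres this is the 10 x 10 grid at
#' `((i + 0.5)/10, (j + 0.5)/10)`.
#'
#' @param n_fibers number of fibres (>= 1).
#' @return an object of class `fiber_template` with `n_fibers`, `seeds`
#'   (n x 2), `kind = "parallel"` and per-fibre Bezier `control_points`.
#' @export
make_parallel_template <- function(n_fibers) {
  if (n_fibers < 1L) stopf("n_fibers must be >= 1")
  g <- ceiling(sqrt(n_fibers))
  centers <- (seq_len(g) - 0.5) / g
  seeds <- as.matrix(expand.grid(x = centers, y = centers))[seq_len(n_fibers), ,
                                                            drop = FALSE]
  dimnames(seeds) <- NULL
  control_points <- lapply(seq_len(n_fibers), function(i) {
    rbind(c(seeds[i, ], 0), c(seeds[i, ], 1))
  })
  structure(list(n_fibers = as.integer(n_fibers), seeds = seeds,
                 kind = "parallel", control_points = control_points),
            class = "fiber_template")
}

# Evaluate a Bezier curve (rows of cp are control points) at parameter t.
bezier_point <- function(cp, t) {
  p <- cp
  while (nrow(p) > 1L) {
    p <- (1 - t) * p[-nrow(p), , drop = FALSE] + t * p[-1L, , drop = FALSE]
  }
  as.vector(p)
}

#' Slice a template with horizontal planes
#'
#' Intersects every fibre curve with the planes `z = level`.  The boundary
#' polygon of each section is the unit-square outline sampled to `n_samples`
#' points (matching the contour resampling count so the correspondence is
#' index-to-index).
#'
#' @param template a `fiber_template`.
#' @param levels strictly increasing values in (0, 1).
#' @param n_samples boundary-polygon sample count (default 64).
#' @return list of `template_section` objects with `level`,
#'   `fiber_points_2d` (n_fibers x 2) and `boundary_polygon` (n_samples x 2).
#' @export
slice_template <- function(template, levels, n_samples = 64L) {
  if (any(levels <= 0) || any(levels >= 1) || is.unsorted(levels, strictly = TRUE)) {
    stopf("levels must be strictly increasing within (0, 1)")
  }
  poly <- unit_square_polygon(n_samples)
  lapply(levels, function(lev) {
    pts <- t(vapply(template$control_points, function(cp) {
      fibre_plane_crossing(cp, lev)
    }, numeric(2L)))
    structure(list(level = lev, fiber_points_2d = pts,
                   boundary_polygon = poly),
              class = "template_section")
  })
}

# (x, y) where the fibre's Bezier curve crosses z = level.
fibre_plane_crossing <- function(cp, level) {
  zfun <- function(t) bezier_point(cp, t)[3L] - level
  z0 <- zfun(0); z1 <- zfun(1)
  if (z0 * z1 > 0) stopf("fibre does not cross the plane z = %g", level)
  if (nrow(cp) == 2L) {       # straight fibre: closed form
    t <- (level - cp[1L, 3L]) / (cp[2L, 3L] - cp[1L, 3L])
  } else {
    t <- stats::uniroot(zfun, c(0, 1), tol = 1e-12)$root
  }
  bezier_point(cp, t)[1:2]
}

# Unit-square outline sampled to n arc-length-uniform 2D points, CCW from
# the origin corner.
unit_square_polygon <- function(n) {
  s <- (seq_len(n) - 1L) / n * 4
  x <- numeric(n); y <- numeric(n)
  side <- floor(s)
  u <- s - side
  x[side == 0] <- u[side == 0];      y[side == 0] <- 0
  x[side == 1] <- 1;                 y[side == 1] <- u[side == 1]
  x[side == 2] <- 1 - u[side == 2];  y[side == 2] <- 1
  x[side == 3] <- 0;                 y[side == 3] <- 1 - u[side == 3]
  cbind(x, y)
}

#' Mean-value coordinates of a point in a simple polygon
#'
#' The generalized barycentric coordinates of Floater: for a point `p`
#' strictly inside a simple polygon with vertices `v_q`, the weight of vertex
#' `q` is `(tan(a_{q-1}/2) + tan(a_q/2)) / |v_q - p|`, normalised to sum to
#' one.  The coordinates are non-negative for convex polygons, reproduce `p`
#' as the weighted vertex combination, and are invariant under affine maps.
#'
#' @param p length-2 numeric point strictly inside the polygon.
#' @param polygon n x 2 matrix of polygon vertices, ordered, simple.
#' @return numeric weight vector of length n summing to 1.
#' @export
mean_value_coordinates <- function(p, polygon) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  if (n < 3L) stopf("polygon needs at least 3 vertices")
  d <- sweep(polygon, 2L, p)
  r <- row_norms(d)
  if (any(r < 1e-13)) stopf("point coincides with a polygon vertex")

  nxt <- c(2:n, 1L)
  crossz <- d[, 1L] * d[nxt, 2L] - d[, 2L] * d[nxt, 1L]
  dotz <- rowSums(d * d[nxt, , drop = FALSE])
  ang <- atan2(crossz, dotz)       # signed angle subtended by edge q -> q+1
  if (any(abs(abs(ang) - pi) < 1e-12)) {
    stopf("point lies on the polygon boundary")
  }
  if (abs(sum(ang)) < pi) {         # winding number 0 => outside
    stopf("point lies outside the polygon")
  }
  tan_half <- tan(ang / 2)
  prev <- c(n, 1:(n - 1L))
  w <- (tan_half[prev] + tan_half) / r
  w / sum(w)
}

#' Map a template section onto a mesh contour
#'
#' Each template fibre point is written in mean-value coordinates with
#' respect to the section's boundary polygon and re-evaluated on the
#' corresponding 3D contour points: `P_i = sum_q lambda_iq c_q`.  By the
#' linear precision of mean-value coordinates this reproduces affine images
#' of the template exactly.
#'
#' @param section a `template_section`.
#' @param contour a `closed_contour` resampled to the same point count as
#'   the section's boundary polygon, correspondence aligned.
#' @return n_fibers x 3 matrix of mapped 3D points.
#' @export
map_section <- function(section, contour) {
  cpts <- contour$points
  if (nrow(cpts) != nrow(section$boundary_polygon)) {
    stopf("contour has %d samples but the template polygon has %d",
          nrow(cpts), nrow(section$boundary_polygon))
  }
  lam <- section_weights(section)
  lam %*% cpts
}

# Cached n_fibers x n_samples mean-value weight matrix for a section.
section_weights <- function(section) {
  if (!is.null(section$weights)) return(section$weights)
  t(apply(section$fiber_points_2d, 1L, mean_value_coordinates,
          polygon = section$boundary_polygon))
}
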