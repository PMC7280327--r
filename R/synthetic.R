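# Parametric synthetic fixtures: tube/fusiform muscle meshes with ring
# attachments, a two-bone toy skeleton, and the hinge-toy closed-form
# oracle.  Everything is deterministic for a fixed seed and sized at
# anatomy-like scales (lengths 0.1-0.4 m, radii 0.01-0.05 m) so tolerances
# transfer to real data.

#' Tube muscle specification
#'
#' @param centerline k x 3 matrix of Bezier control points (m); default a
#'   straight 0.2 m segment along +z.
#' @param radius constant tube radius (m), ignored when `r_min`/`r_max`
#'   given.
#' @param r_min,r_max optional fusiform profile
#'   `r(t) = r_min + (r_max - r_min) * sin(pi t)`.
#' @param n_circumferential,n_axial resolution (>= 8 and >= 4).
#' @param jitter optional vertex noise amplitude (m) applied to interior
#'   side-wall vertices.
#' @param seed integer seed for the jitter.
#' @return object of class `tube_spec`.
#' @export
tube_spec <- function(centerline = rbind(c(0, 0, 0), c(0, 0, 0.2)),
                      radius = 0.03, r_min = NULL, r_max = NULL,
                      n_circumferential = 32L, n_axial = 20L,
                      jitter = 0, seed = 1L) {
  if (n_circumferential < 8L || n_axial < 4L) {
    stopf("resolution must be >= 8 circumferential and >= 4 axial")
  }
  fusiform <- !is.null(r_min) && !is.null(r_max)
  if (fusiform && (r_min <= 0 || r_max < r_min)) {
    stopf("fusiform profile needs 0 < r_min <= r_max")
  }
  if (!fusiform && radius <= 0) stopf("radius must be > 0")
  structure(list(centerline = as.matrix(centerline), radius = radius,
                 r_min = r_min, r_max = r_max, fusiform = fusiform,
                 n_circumferential = as.integer(n_circumferential),
                 n_axial = as.integer(n_axial), jitter = jitter,
                 seed = as.integer(seed)),
            class = "tube_spec")
}

tube_radius_at <- function(spec, t) {
  if (spec$fusiform) spec$r_min + (spec$r_max - spec$r_min) * sin(pi * t)
  else rep(spec$radius, length(t))
}

#' Generate a watertight tube/fusiform muscle with ring attachments
#'
#' Sweeps rings of `n_circumferential` vertices along the (Bezier)
#' centerline with parallel-transported frames, closes both ends with
#' triangle-fan caps, and places attachment landmark rings on the cap
#' perimeters (12 landmarks each).  Deterministic for a fixed seed.
#'
#' @param spec a [tube_spec()].
#' @param name mesh name.
#' @return list with `mesh` ([trimesh()]), `origin` and `insertion`
#'   ([attachment_area()]s on the z = 0 / z = max caps).
#' @export
make_tube_muscle <- function(spec = tube_spec(), name = "tube_muscle") {
  nc <- spec$n_circumferential
  na_ <- spec$n_axial
  t_ax <- (seq_len(na_) - 1L) / (na_ - 1L)
  centers <- t(vapply(t_ax, function(t) bezier_point(spec$centerline, t),
                      numeric(3L)))
  radii <- tube_radius_at(spec, t_ax)

  # parallel-transported frames along the centerline
  tangents <- rbind(centers[2L, ] - centers[1L, ],
                    (centers[-1L, , drop = FALSE] -
                       centers[-na_, , drop = FALSE]))
  tangents <- tangents / row_norms(tangents)
  e1 <- perp_vector(tangents[1L, ])
  frames <- vector("list", na_)
  for (k in seq_len(na_)) {
    if (k > 1L) {
      # rotate previous e1 into the new tangent plane
      e1 <- e1 - sum(e1 * tangents[k, ]) * tangents[k, ]
      e1 <- normalize(e1)
    }
    frames[[k]] <- list(e1 = e1, e2 = cross3(tangents[k, ], e1))
  }
  if (min(radii) <= 0) stopf("tube radius must stay positive")
  # crude self-intersection guard: rings must be shorter than the local
  # centerline bend radius
  seg <- row_norms(centers[-1L, , drop = FALSE] - centers[-na_, , drop = FALSE])
  if (any(seg < 1e-12)) stopf("degenerate centerline")

  ang <- (seq_len(nc) - 1L) / nc * 2 * pi
  verts <- matrix(0, na_ * nc, 3L)
  for (k in seq_len(na_)) {
    ring <- centers[rep(k, nc), ] +
      radii[k] * (outer(cos(ang), frames[[k]]$e1) +
                    outer(sin(ang), frames[[k]]$e2))
    verts[(k - 1L) * nc + seq_len(nc), ] <- ring
  }
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    noise <- matrix(stats::rnorm(length(verts), sd = spec$jitter),
                    ncol = 3L)
    interior <- rep(seq_len(na_), each = nc) %in% 2:(na_ - 1L)
    verts[interior, ] <- verts[interior, ] + noise[interior, ]
  }

  faces <- list()
  vid <- function(k, j) (k - 1L) * nc + ((j - 1L) %% nc) + 1L
  for (k in seq_len(na_ - 1L)) {
    for (j in seq_len(nc)) {
      a <- vid(k, j); b <- vid(k, j + 1L)
      c_ <- vid(k + 1L, j); d <- vid(k + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, b, d)
      faces[[length(faces) + 1L]] <- c(a, d, c_)
    }
  }
  # caps: fans to the ring centroids
  c0 <- nrow(verts) + 1L
  c1 <- nrow(verts) + 2L
  verts <- rbind(verts, centers[1L, ], centers[na_, ])
  for (j in seq_len(nc)) {
    faces[[length(faces) + 1L]] <- c(c0, vid(1L, j + 1L), vid(1L, j))
    faces[[length(faces) + 1L]] <- c(c1, vid(na_, j), vid(na_, j + 1L))
  }
  mesh <- trimesh(verts, do.call(rbind, faces), name = name)

  ring_landmarks <- function(k) {
    sel <- seq(1L, nc, length.out = 13L)[1:12]
    verts[vid(k, round(sel)), , drop = FALSE]
  }
  list(mesh = mesh,
       origin = attachment_area("origin", "parent_bone", ring_landmarks(1L)),
       insertion = attachment_area("insertion", "child_bone",
                                   ring_landmarks(na_)))
}

#' Two-bone toy skeleton with a ball-and-socket joint
#'
#' A fixed parent box below the joint centre and an articulated child box
#' above it, arranged along the z axis so a tube muscle generated by
#' [make_tube_muscle()] (z = 0 to 0.2 m) has its origin near the parent and
#' its insertion near the child, mimicking a pelvis/femur pair at desk
#' scale.
#'
#' @param center 3D joint centre (m); the default sits just above the
#'   standard tube muscle.
#' @param parent_size,child_size box edge-length triples (m).
#' @param coord_ranges optional coordinate ranges forwarded to [skeleton()].
#' @return a [skeleton()] with bones `parent_bone` and `child_bone`.
#' @export
make_two_bone_skeleton <- function(center = c(0, 0, 0.25),
                                   parent_size = c(0.10, 0.10, 0.20),
                                   child_size = c(0.06, 0.06, 0.20),
                                   coord_ranges = NULL) {
  parent <- box_mesh(center + c(0, 0, -0.32), parent_size, "parent_bone")
  child <- box_mesh(center + c(0, 0, 0.13), child_size, "child_bone")
  skeleton(list(parent_bone = parent, child_bone = child),
           joint_center = center, parent = "parent_bone",
           child = "child_bone", coord_ranges = coord_ranges)
}

# Axis-aligned box as a 12-triangle mesh.
box_mesh <- function(center, size, name) {
  h <- size / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * rep(h, each = 8L), 2L, center, `+`)
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z-
             c(5, 6, 8), c(5, 8, 7),   # z+
             c(1, 2, 6), c(1, 6, 5),   # y-
             c(3, 7, 8), c(3, 8, 4),   # y+
             c(1, 5, 7), c(1, 7, 3),   # x-
             c(2, 4, 8), c(2, 8, 6))   # x+
  trimesh(v, f, name = name)
}

#' Hinge-toy specification
#'
#' A planar two-segment toy: attachment points at distances `a` (parent) and
#' `b` (child) from the joint centre, rest included angle `theta0`.  Its
#' length and tendon-excursion moment arm have closed forms, making it the
#' independent oracle for the excursion machinery.
#'
#' @param a,b attachment distances from the joint centre (m).
#' @param theta0 rest included angle (degrees).
#' @return object of class `hinge_toy`.
#' @export
hinge_toy <- function(a = 0.1, b = 0.1, theta0 = 90) {
  if (a <= 0 || b <= 0) stopf("hinge arms must be positive")
  structure(list(a = a, b = b, theta0 = theta0), class = "hinge_toy")
}

#' Closed-form hinge length and moment arm
#'
#' `l = sqrt(a^2 + b^2 - 2 a b cos(theta0 + theta))` and moment-arm
#' magnitude `a b sin(theta0 + theta) / l` (law of cosines and its
#' derivative).
#'
#' @param toy a [hinge_toy()].
#' @param theta joint angle(s) in degrees; requires
#'   `0 < theta0 + theta < 180`.
#' @return list with vectors `length` (m) and `moment_arm` (m, magnitude).
#' @export
hinge_oracle <- function(toy, theta) {
  phi <- deg2rad(toy$theta0 + theta)
  if (any(phi <= 0) || any(phi >= pi)) {
    stopf("theta0 + theta must stay within (0, 180) degrees")
  }
  l <- sqrt(toy$a^2 + toy$b^2 - 2 * toy$a * toy$b * cos(phi))
  list(length = l, moment_arm = toy$a * toy$b * sin(phi) / l)
}

#' Build the hinge toy as a fibre, a path and a skeleton
#'
#' Embeds the toy in a [make_two_bone_skeleton()]: the parent point `P` at
#' distance `a` along +y from the joint centre, the child rest point at
#' included angle `theta0` from `P`'s direction in the flexion (x-y) plane.
#' Flexion by `theta` makes the included angle `theta0 + theta`.  Returns
#' both representations so the excursion and geometric methods can be
#' compared on identical geometry.
#'
#' @param toy a [hinge_toy()].
#' @param center joint centre (m).
#' @return list with `skeleton`, `fibers` (bound 2-point `fiber_set`),
#'   `path` ([polyline_path()]), and `axis` (flexion axis, +z).
#' @export
make_hinge_fixture <- function(toy = hinge_toy(), center = c(0, 0, 0)) {
  skel <- make_two_bone_skeleton(center)
  phi0 <- deg2rad(toy$theta0)
  P <- center + toy$a * c(0, 1, 0)
  D <- center + toy$b * c(-sin(phi0), cos(phi0), 0)
  pts <- array(0, dim = c(1L, 2L, 3L))
  pts[1L, 1L, ] <- P
  pts[1L, 2L, ] <- D
  fib <- fiber_set(pts, muscle = "hinge_toy")
  fib$bindings <- list(
    bones = array(c("parent_bone", "parent_bone", "child_bone", "child_bone"),
                  dim = c(1L, 2L, 2L)),
    w = array(c(1, 0, 0, 1), dim = c(1L, 2L, 2L)),
    a = 0)
  path <- polyline_path(list(path_point("parent_bone", P),
                             path_point("child_bone", D)),
                        name = "hinge_toy")
  list(skeleton = skel, fibers = fib, path = path, axis = c(0, 0, 1))
}
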