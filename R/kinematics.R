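# Rigid-bone skeleton with a ball-and-socket joint, quadratic blending
# weights, and fibre-point pose updates.
#
# A fibre point V_i is animated as a blend of the rigid transforms of its
# two nearest bones:  V'_i = sum_j w_ij (R_j V_i + T_j),  with the origin
# bone's weight given by the quadratic  f(t) = a t^2 - (a + 1) t + 1  of the
# point's relative position t = (i - 1)/(n - 1) along the fibre.  f(0) = 1
# and f(1) = 0, so the first and last points move rigidly with their bones.

#' Rigid transform
#'
#' @param R 3 x 3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation (m).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (max(abs(R %*% t(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stopf("R is not a proper rotation matrix")
  }
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

apply_transform <- function(tf, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  sweep(points %*% t(tf$R), 2L, tf$t, `+`)
}

#' Two-bone skeleton with a ball-and-socket joint
#'
#' @param bones named list of [trimesh()] bone surfaces (rest pose).
#' @param joint_center 3D joint centre (m), e.g. from [fit_sphere()].
#' @param parent,child names of the fixed (parent) and articulated (child)
#'   bones.
#' @param coord_ranges named list of `c(lo, hi)` coordinate ranges in
#'   degrees; defaults to hip-like ranges.
#' @return object of class `skeleton`.
#' @export
skeleton <- function(bones, joint_center, parent, child,
                     coord_ranges = NULL) {
  if (!all(c(parent, child) %in% names(bones))) {
    stopf("parent/child must name bones in `bones`")
  }
  if (any(!is.finite(joint_center))) stopf("joint centre must be finite")
  coord_ranges <- coord_ranges %||% list(flexion = c(-10, 60),
                                         adduction = c(-40, 40),
                                         rotation = c(-30, 30))
  structure(list(bones = bones, joint = list(center = as.numeric(joint_center),
                                             parent = parent, child = child,
                                             rotation_order = "ZXY"),
                 coord_ranges = coord_ranges),
            class = "skeleton")
}

#' Ball-and-socket joint pose
#'
#' @param flexion,adduction,rotation joint angles in degrees
#'   (flexion about Z, adduction about X, internal rotation about Y,
#'   composed body-fixed Z-X-Y).
#' @return named numeric vector of class `joint_pose`.
#' @export
joint_pose <- function(flexion = 0, adduction = 0, rotation = 0) {
  p <- c(flexion = flexion, adduction = adduction, rotation = rotation)
  if (any(!is.finite(p))) stopf("joint angles must be finite")
  structure(p, class = "joint_pose")
}

rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

#' Quadratic blending-weight function
#'
#' `w1 = f(t) = a t^2 - (a + 1) t + 1`, `w2 = 1 - w1`.  The boundary
#' conditions f(0) = 1, f(1) = 0 leave a single muscle-specific parameter
#' `a` controlling how quickly the origin bone's influence fades along the
#' fibre.
#'
#' @param a muscle-specific parameter (dimensionless).  Fitted values
#'   shipped with [muscle_weight_params()]: psoas -0.042, iliacus -0.024,
#'   gluteus maximus -0.042, gluteus medius 0.0.
#' @param t relative position(s) along the fibre in \[0, 1\].
#' @return list with vectors `w1` and `w2`.
#' @export
weight_function <- function(a, t) {
  if (any(t < 0 | t > 1)) stopf("t must lie in [0, 1]")
  w1 <- a * t^2 - (a + 1) * t + 1
  list(w1 = w1, w2 = 1 - w1)
}

#' Shipped per-muscle blending parameters
#'
#' @return named numeric vector of the fitted `a` values.
#' @export
muscle_weight_params <- function() {
  c(psoas = -0.042, iliacus = -0.024,
    gluteus_maximus = -0.042, gluteus_medius = 0.0)
}

#' Bind fibre points to their two nearest bones
#'
#' For each fibre point the two bones with the smallest point-to-surface
#' distance in the rest pose are selected; the bone closest to the fibre's
#' first point takes the origin-side weight `w1 = f(t)`, with
#' `t = (i - 1)/(n - 1)` measured from the fibre origin.
#'
#' @param fibers a `fiber_set` in the rest pose.
#' @param skel a [skeleton()] with at least two bones.
#' @param a blending parameter passed to [weight_function()].
#' @param origin_bone optional bone name the fibre origins attach to; when
#'   `NULL` it is inferred as the bone nearest each fibre's first point.
#' @return the `fiber_set` with a `bindings` field: list of `bones`
#'   (n_fibers x n_points x 2 bone-name array) and `w` (matching weights).
#' @export
assign_bones <- function(fibers, skel, a = 0, origin_bone = NULL) {
  if (length(skel$bones) < 2L) stopf("assign_bones needs at least two bones")
  n <- fibers$n_fibers
  np <- fibers$n_points
  pts <- matrix(aperm(fibers$points, c(2L, 1L, 3L)), ncol = 3L)  # point-major

  dists <- vapply(skel$bones, function(b) {
    closest_point_on_mesh(pts, b)$distance
  }, numeric(nrow(pts)))
  if (is.null(dim(dists))) dists <- matrix(dists, nrow = 1L)

  bone_names <- names(skel$bones)
  t_rel <- (seq_len(np) - 1L) / (np - 1L)
  w1 <- weight_function(a, t_rel)$w1

  bones_arr <- array("", dim = c(n, np, 2L))
  w_arr <- array(0, dim = c(n, np, 2L))
  for (i in seq_len(n)) {
    rows <- (i - 1L) * np + seq_len(np)
    drow <- dists[rows, , drop = FALSE]
    # origin-side bone: declared, or nearest to the fibre's first point
    b_origin <- origin_bone %||% bone_names[which.min(drow[1L, ])]
    for (k in seq_len(np)) {
      nearest2 <- bone_names[order(drow[k, ])[1:2]]
      if (!b_origin %in% nearest2) nearest2[2L] <- b_origin
      other <- setdiff(nearest2, b_origin)[1L]
      bones_arr[i, k, ] <- c(b_origin, other)
      w_arr[i, k, ] <- c(w1[k], 1 - w1[k])
    }
  }
  fibers$bindings <- list(bones = bones_arr, w = w_arr, a = a)
  fibers
}

#' Per-bone rigid transforms for a joint pose
#'
#' The parent bone is fixed (identity).  The child rotates about the joint
#' centre `c` with the body-fixed composition `R = Rz(flexion) Rx(adduction)
#' Ry(rotation)`; the translation `T = c - R c` keeps the joint centre a
#' fixed point.
#'
#' @param skel a [skeleton()].
#' @param pose a [joint_pose()] (degrees).
#' @return named list of [rigid_transform()]s, one per bone.
#' @export
pose_transforms <- function(skel, pose) {
  check_pose_ranges(skel, pose)
  ang <- deg2rad(unclass(pose))
  R <- rot_z(ang[["flexion"]]) %*% rot_x(ang[["adduction"]]) %*%
    rot_y(ang[["rotation"]])
  cen <- skel$joint$center
  tf <- stats::setNames(vector("list", length(skel$bones)), names(skel$bones))
  for (b in names(skel$bones)) {
    tf[[b]] <- if (b == skel$joint$child) {
      rigid_transform(R, cen - as.vector(R %*% cen))
    } else {
      rigid_transform()
    }
  }
  tf
}

check_pose_ranges <- function(skel, pose) {
  for (nm in names(skel$coord_ranges)) {
    v <- unclass(pose)[[nm]]
    rng <- skel$coord_ranges[[nm]]
    if (!is.null(v) && (v < rng[1L] - 1e-9 || v > rng[2L] + 1e-9)) {
      stopf("pose coordinate '%s' = %g outside range [%g, %g] degrees",
            nm, v, rng[1L], rng[2L])
    }
  }
  invisible(TRUE)
}

#' Update fibre geometry to a new pose
#'
#' Applies the blended-transform formula
#' `V'_i = sum_j w_ij (R_j V_i + T_j)` to every fibre point.  The rest
#' geometry is untouched; a new posed `fiber_set` is returned.
#'
#' @param fibers a `fiber_set` with bindings from [assign_bones()].
#' @param transforms named list of [rigid_transform()]s per bone, from
#'   [pose_transforms()].
#' @return the posed `fiber_set`.
#' @export
update_fibers <- function(fibers, transforms) {
  if (is.null(fibers$bindings)) {
    stopf("update_fibers: fibre set has no bone bindings; call assign_bones()")
  }
  n <- fibers$n_fibers
  np <- fibers$n_points
  pts <- matrix(aperm(fibers$points, c(2L, 1L, 3L)), ncol = 3L)
  bones <- matrix(aperm(fibers$bindings$bones, c(2L, 1L, 3L)), ncol = 2L)
  w <- matrix(aperm(fibers$bindings$w, c(2L, 1L, 3L)), ncol = 2L)
  if (!all(unique(as.vector(bones)) %in% names(transforms))) {
    stopf("update_fibers: missing transform for a bound bone")
  }

  # transform all points under every bone once, then blend
  imgs <- lapply(transforms, apply_transform, points = pts)
  out <- matrix(0, nrow(pts), 3L)
  for (j in 1:2) {
    for (b in names(transforms)) {
      sel <- bones[, j] == b
      if (any(sel)) {
        out[sel, ] <- out[sel, , drop = FALSE] +
          w[sel, j] * imgs[[b]][sel, , drop = FALSE]
      }
    }
  }
  posed <- fibers
  posed$points <- aperm(array(out, dim = c(np, n, 3L)), c(2L, 1L, 3L))
  posed
}

# Closest surface point and distance from each query point to a mesh.
closest_point_on_mesh <- function(points, mesh) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  v <- mesh$vertices
  f <- mesh$faces
  npq <- nrow(points)
  best_d2 <- rep(Inf, npq)
  best_p <- matrix(0, npq, 3L)
  for (fi in seq_len(nrow(f))) {
    tri <- v[f[fi, ], , drop = FALSE]
    cp <- closest_point_on_triangle(points, tri)
    d2 <- rowSums((points - cp)^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_p[upd, ] <- cp[upd, , drop = FALSE]
    }
  }
  list(point = best_p, distance = sqrt(best_d2))
}

# Vectorised closest point on one triangle for many query points: project to
# the plane, clamp to the triangle via barycentric signs, else nearest edge.
closest_point_on_triangle <- function(p, tri) {
  a <- tri[1L, ]; b <- tri[2L, ]; c_ <- tri[3L, ]
  ab <- b - a; ac <- c_ - a
  n <- cross3(ab, ac)
  nn <- sum(n * n)
  if (nn < 1e-300) {  # degenerate triangle: fall back to edge distances
    return(closest_point_on_segment(p, a, b))
  }
  ap <- sweep(p, 2L, a)
  # barycentric coordinates of the plane projection
  d00 <- sum(ab * ab); d01 <- sum(ab * ac); d11 <- sum(ac * ac)
  d20 <- ap %*% ab; d21 <- ap %*% ac
  denom <- d00 * d11 - d01 * d01
  vb <- (d11 * d20 - d01 * d21) / denom
  wb <- (d00 * d21 - d01 * d20) / denom
  ub <- 1 - vb - wb
  inside <- ub >= 0 & vb >= 0 & wb >= 0
  out <- matrix(0, nrow(p), 3L)
  if (any(inside)) {
    out[inside, ] <- outer(ub[inside], a) + outer(vb[inside], b) +
      outer(wb[inside], c_)
  }
  if (any(!inside)) {
    q <- p[!inside, , drop = FALSE]
    e1 <- closest_point_on_segment(q, a, b)
    e2 <- closest_point_on_segment(q, b, c_)
    e3 <- closest_point_on_segment(q, a, c_)
    d1 <- rowSums((q - e1)^2)
    d2 <- rowSums((q - e2)^2)
    d3 <- rowSums((q - e3)^2)
    pick <- cbind(d1, d2, d3)
    sel <- max.col(-pick, ties.method = "first")
    res <- e1
    res[sel == 2L, ] <- e2[sel == 2L, , drop = FALSE]
    res[sel == 3L, ] <- e3[sel == 3L, , drop = FALSE]
    out[!inside, ] <- res
  }
  out
}

closest_point_on_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab * ab)
  if (len2 < 1e-300) return(matrix(a, nrow(p), 3L, byrow = TRUE))
  t <- pmin(1, pmax(0, sweep(p, 2L, a) %*% ab / len2))
  sweep(outer(as.vector(t), ab), 2L, a, `+`)
}
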