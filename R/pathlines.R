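# Minimal straight-lines musculotendon path model: via points, conditional
# via points, and the geometric (cross-product) moment arm.  This is the
# comparison model for the fibre decomposition: conventional polyline paths
# whose conditional points switch off outside a joint-angle range, making
# the length (and excursion-based moment arm) non-smooth; the geometric
# method stays exact at those toggles.

#' Path point (via point)
#'
#' @param bone bone the point is fixed on.
#' @param position 3D position in the bone's rest frame (m).
#' @param condition optional list `list(coordinate = <name>, range =
#'   c(lo, hi))` in degrees; the point is active only when the coordinate
#'   lies inside the closed interval.
#' @return object of class `path_point`.
#' @export
path_point <- function(bone, position, condition = NULL) {
  if (!is.null(condition)) {
    if (is.null(condition$coordinate) || length(condition$range) != 2L ||
        condition$range[1L] >= condition$range[2L]) {
      stopf("condition must be list(coordinate=, range=c(lo, hi)) with lo < hi")
    }
  }
  structure(list(bone = bone, position = as.numeric(position),
                 condition = condition),
            class = "path_point")
}

#' Straight-lines musculotendon path
#'
#' @param points list of [path_point()]s ordered origin to insertion.  The
#'   first and last must be unconditional, and at least two points must be
#'   unconditionally active.
#' @param name path identifier.
#' @return object of class `polyline_path`.
#' @export
polyline_path <- function(points, name = "path") {
  if (length(points) < 2L) stopf("a path needs at least 2 points")
  uncond <- vapply(points, function(p) is.null(p$condition), TRUE)
  if (!uncond[1L] || !uncond[length(points)]) {
    stopf("first and last path points must be unconditional")
  }
  structure(list(points = points, name = name), class = "polyline_path")
}

#' Active world-space path points at a pose
#'
#' Conditional via points are included iff their coordinate value lies in
#' the closed interval `[lo, hi]`; retained points are transformed to world
#' space by their bone's pose transform.
#'
#' @param path a [polyline_path()].
#' @param skel a [skeleton()].
#' @param pose a [joint_pose()].
#' @return matrix of world-space points (rows ordered origin to insertion)
#'   with a `bones` attribute naming each point's bone.
#' @export
active_points <- function(path, skel, pose) {
  tf <- pose_transforms(skel, pose)
  keep <- vapply(path$points, function(p) {
    if (is.null(p$condition)) return(TRUE)
    v <- unclass(pose)[[p$condition$coordinate]]
    if (is.null(v)) stopf("pose lacks coordinate '%s'", p$condition$coordinate)
    v >= p$condition$range[1L] && v <= p$condition$range[2L]
  }, TRUE)
  pts <- path$points[keep]
  if (length(pts) < 2L) stopf("fewer than 2 active path points at this pose")
  world <- t(vapply(pts, function(p) {
    as.vector(apply_transform(tf[[p$bone]], p$position))
  }, numeric(3L)))
  attr(world, "bones") <- vapply(pts, `[[`, "", "bone")
  world
}

#' Polyline path length
#'
#' @param points world-space point matrix (>= 2 rows).
#' @return total Euclidean length (m).
#' @export
path_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stopf("path_length needs at least 2 points")
  sum(row_norms(points[-1L, , drop = FALSE] -
                  points[-nrow(points), , drop = FALSE]))
}

#' Geometric moment arm of a straight-lines path
#'
#' For the single path segment spanning the joint (parent-fixed point `P` to
#' child-fixed point `D`), the moment arm about the unit axis `a` through the
#' joint centre `c` is `r = a . ((D - c) x u)` with `u` the unit vector from
#' `D` toward `P`.  Positive `r` means muscle tension generates a positive
#' moment about `a`.  Unlike tendon excursion this stays exact when
#' conditional via points toggle, which is why it is the method of choice
#' for the straight-lines comparison model.
#'
#' @param path a [polyline_path()] crossing the joint exactly once.
#' @param skel a [skeleton()].
#' @param pose a [joint_pose()].
#' @param axis unit 3-vector of the joint axis in world space.
#' @return signed moment arm (m).
#' @export
geometric_moment_arm <- function(path, skel, pose, axis = c(0, 0, 1)) {
  world <- active_points(path, skel, pose)
  bones <- attr(world, "bones")
  parent <- skel$joint$parent
  child <- skel$joint$child
  spans <- which(bones[-length(bones)] != bones[-1L])
  if (length(spans) != 1L) {
    stopf("path must cross the joint exactly once (found %d crossings)",
          length(spans))
  }
  i <- spans
  if (bones[i] == parent && bones[i + 1L] == child) {
    P <- world[i, ]; D <- world[i + 1L, ]
  } else if (bones[i] == child && bones[i + 1L] == parent) {
    D <- world[i, ]; P <- world[i + 1L, ]
  } else {
    stopf("spanning segment does not connect parent to child")
  }
  len <- vnorm(P - D)
  if (len < 1e-12) stopf("zero-length spanning segment")
  u <- (P - D) / len
  sum(normalize(axis) * cross3(D - skel$joint$center, u))
}

#' Detect conditional-point toggles along a pose sweep
#'
#' Reports the poses at which the set of active via points changes (where
#' path length and excursion moment arms are non-smooth).
#'
#' @param path a [polyline_path()].
#' @param skel a [skeleton()].
#' @param coordinate swept coordinate name.
#' @param angles_deg vector of sweep angles (degrees).
#' @return integer indices into `angles_deg` after which the active set
#'   changes (empty when the length is smooth everywhere).
#' @export
path_toggle_poses <- function(path, skel, coordinate, angles_deg) {
  active <- vapply(angles_deg, function(th) {
    args <- stats::setNames(list(th), coordinate)
    pose <- do.call(joint_pose, args)
    paste(vapply(path$points, function(p) {
      if (is.null(p$condition)) return("1")
      v <- unclass(pose)[[p$condition$coordinate]]
      if (v >= p$condition$range[1L] && v <= p$condition$range[2L]) "1" else "0"
    }, ""), collapse = "")
  }, "")
  which(active[-1L] != active[-length(active)])
}
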