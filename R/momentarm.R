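# Length-angle curves, quartic smoothing, tendon-excursion moment arms,
# fan summaries and the range-agreement metric.
#
# The tendon-excursion method estimates a fibre's moment arm about a joint
# coordinate as the derivative of its length with respect to the joint
# angle.  Lengths are sampled on a uniform pose grid, interpolated with a
# 4th-order polynomial, and differentiated analytically.  Sign convention:
# a muscle that SHORTENS as the coordinate increases generates a positive
# moment about it, so the default reported moment arm is r = -dl/dtheta
# (configurable via `sign`).

default_sweep_ranges <- function() {
  list(flexion = c(-10, 60), adduction = c(-40, 40), rotation = c(-30, 30))
}

#' Sweep fibre lengths over a joint coordinate
#'
#' Poses the skeleton on a uniform grid over one coordinate (the others held
#' at zero), updates the fibre geometry at each pose and records per-fibre
#' polyline lengths.  Also accepts a [polyline_path()], whose active-point
#' length is recorded as a single "fibre".
#'
#' @param fibers a `fiber_set` with bindings, or a [polyline_path()].
#' @param skel a [skeleton()].
#' @param coordinate `"flexion"`, `"adduction"` or `"rotation"`.
#' @param range `c(lo, hi)` in degrees; defaults to the standard hip task
#'   ranges (flexion -10..60, adduction -40..40, rotation -30..30).
#' @param step grid step in degrees (default 2).
#' @return object of class `length_curve`: `coordinate`, `theta_deg`,
#'   `lengths` (n_fibers x n_poses, m), and empty `fit` slot.
#' @export
sweep_lengths <- function(fibers, skel, coordinate = "flexion",
                          range = NULL, step = 2) {
  coordinate <- match.arg(coordinate, c("flexion", "adduction", "rotation"))
  range <- range %||% default_sweep_ranges()[[coordinate]]
  if (step <= 0) stopf("step must be > 0")
  if (range[2L] <= range[1L]) stopf("range must satisfy hi > lo")
  theta <- seq(range[1L], range[2L], by = step)

  lengths <- vapply(theta, function(th) {
    args <- stats::setNames(list(th), coordinate)
    pose <- do.call(joint_pose, args)
    tryCatch({
      if (inherits(fibers, "polyline_path")) {
        path_length(active_points(fibers, skel, pose))
      } else {
        posed <- update_fibers(fibers, pose_transforms(skel, pose))
        fiber_lengths(posed)
      }
    }, error = function(e) {
      stopf("sweep failed at %s = %g deg: %s", coordinate, th,
            conditionMessage(e))
    })
  }, numeric(if (inherits(fibers, "polyline_path")) 1L else fibers$n_fibers))
  if (is.null(dim(lengths))) lengths <- matrix(lengths, nrow = 1L)
  if (any(lengths <= 0)) stopf("non-positive fibre length encountered")
  structure(list(coordinate = coordinate, theta_deg = theta,
                 lengths = lengths, fit = NULL),
            class = "length_curve")
}

#' Fit 4th-order polynomials to length-angle curves
#'
#' Least-squares degree-4 fit per fibre, in radians and centred on the grid
#' midpoint for well-scaled coefficients.  Residuals are recorded.
#'
#' @param curve a `length_curve` with at least 5 samples.
#' @return the curve with `fit = list(coef (n_fibers x 5), center_rad,
#'   residual)` filled in.
#' @export
fit_quartic <- function(curve) {
  theta <- deg2rad(curve$theta_deg)
  if (length(theta) < 5L) stopf("fit_quartic needs >= 5 samples")
  x <- theta - mean(theta)
  X <- outer(x, 0:4, `^`)
  qr_x <- qr(X)
  if (qr_x$rank < 5L) stopf("fit_quartic: rank-deficient design")
  coef <- t(qr.coef(qr_x, t(curve$lengths)))
  if (is.null(dim(coef))) coef <- matrix(coef, nrow = 1L)
  resid <- curve$lengths - coef %*% t(X)
  curve$fit <- list(coef = coef, center_rad = mean(theta),
                    residual = max(abs(resid)))
  curve
}

#' Tendon-excursion moment arms
#'
#' Differentiates the fitted quartic analytically at each grid pose:
#' `r = sign * dl/dtheta` (metres per radian, i.e. metres).  The default
#' `sign = -1` reports moment-generating moment arms (a coordinate's agonist
#' shortens as the coordinate increases).
#'
#' @param curve a `length_curve` after [fit_quartic()] (fitted on demand).
#' @param sign +1 or -1 (default -1).
#' @return object of class `momentarm_curve`: `coordinate`, `theta_deg`,
#'   `r` (n_fibers x n_poses, m), `sign`.
#' @export
excursion_moment_arms <- function(curve, sign = -1) {
  if (!sign %in% c(-1, 1)) stopf("sign must be +1 or -1")
  if (is.null(curve$fit)) curve <- fit_quartic(curve)
  x <- deg2rad(curve$theta_deg) - curve$fit$center_rad
  dX <- cbind(rep(0, length(x)), 1, 2 * x, 3 * x^2, 4 * x^3)
  r <- sign * (curve$fit$coef %*% t(dX))
  structure(list(coordinate = curve$coordinate, theta_deg = curve$theta_deg,
                 r = r, sign = sign),
            class = "momentarm_curve")
}

#' Summarise a moment-arm fan
#'
#' Per-pose envelope (min/max over fibres) plus global minimum, maximum,
#' mean and population standard deviation over all fibre-pose samples,
#' reported in centimetres.
#'
#' @param ma a `momentarm_curve`.
#' @return object of class `fan_summary`: `theta_deg`, `lo_cm`, `hi_cm`
#'   (per-pose envelope) and `min_cm`, `max_cm`, `mean_cm`, `sd_cm`.
#' @export
summarize_fan <- function(ma) {
  r_cm <- ma$r * 100
  if (length(r_cm) == 0L) stopf("summarize_fan: empty moment-arm curve")
  structure(list(theta_deg = ma$theta_deg,
                 lo_cm = apply(r_cm, 2L, min),
                 hi_cm = apply(r_cm, 2L, max),
                 min_cm = min(r_cm), max_cm = max(r_cm),
                 mean_cm = mean(r_cm), sd_cm = sd_pop(r_cm)),
            class = "fan_summary")
}

#' @export
print.fan_summary <- function(x, ...) {
  cat(sprintf("<fan_summary: min %.1f, max %.1f, mean %.1f (sd %.1f) cm over %d poses>\n",
              x$min_cm, x$max_cm, x$mean_cm, x$sd_cm, length(x$theta_deg)))
  invisible(x)
}

#' Range-agreement percentage against a reference curve
#'
#' The percentage of poses at which the reference moment arm lies inside the
#' fan's per-pose `[min, max]` envelope (inclusive bounds), rounded to the
#' nearest integer percent.
#'
#' @param ma a `momentarm_curve` (the fan).
#' @param reference numeric vector of reference moment arms (same units as
#'   `ma$r`), one per grid pose.
#' @return integer percentage in 0..100.
#' @export
range_agreement <- function(ma, reference) {
  npose <- ncol(ma$r)
  if (length(reference) != npose) {
    stopf("reference has %d values but the fan has %d poses",
          length(reference), npose)
  }
  lo <- apply(ma$r, 2L, min)
  hi <- apply(ma$r, 2L, max)
  inside <- reference >= lo & reference <= hi
  as.integer(round(100 * sum(inside) / npose))
}

#' Export per-pose per-fibre moment arms to CSV
#'
#' Columns: `coordinate, pose_deg, fiber_id, moment_arm_cm`.
#'
#' @param ma a `momentarm_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_momentarm_csv <- function(ma, path) {
  n <- nrow(ma$r)
  npose <- ncol(ma$r)
  df <- data.frame(coordinate = ma$coordinate,
                   pose_deg = rep(ma$theta_deg, each = n),
                   fiber_id = rep(seq_len(n), times = npose),
                   moment_arm_cm = as.vector(ma$r) * 100)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
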