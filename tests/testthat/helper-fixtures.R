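# Programmatic fixtures shared across the test files.  Everything is built
# in code; no binary data.

vnorm_test <- function(v) sqrt(sum(v^2))

# Open cylinder side wall (no caps): radius r, height H, axis +z.
open_cylinder <- function(n_c = 24L, n_a = 12L, r = 0.03, H = 0.2) {
  z <- seq(0, H, length.out = n_a)
  ang <- (seq_len(n_c) - 1L) / n_c * 2 * pi
  verts <- do.call(rbind, lapply(z, function(zz) {
    cbind(r * cos(ang), r * sin(ang), zz)
  }))
  vid <- function(k, j) (k - 1L) * n_c + ((j - 1L) %% n_c) + 1L
  faces <- list()
  for (k in seq_len(n_a - 1L)) {
    for (j in seq_len(n_c)) {
      faces[[length(faces) + 1L]] <- c(vid(k, j), vid(k, j + 1L), vid(k + 1L, j + 1L))
      faces[[length(faces) + 1L]] <- c(vid(k, j), vid(k + 1L, j + 1L), vid(k + 1L, j))
    }
  }
  trimesh(verts, do.call(rbind, faces), name = "open_cylinder")
}

# Flat annulus in the z = 0 plane: two boundary loops of n_c vertices each.
annulus_mesh <- function(n_c = 16L, r_in = 0.01, r_out = 0.03) {
  ang <- (seq_len(n_c) - 1L) / n_c * 2 * pi
  verts <- rbind(cbind(r_in * cos(ang), r_in * sin(ang), 0),
                 cbind(r_out * cos(ang), r_out * sin(ang), 0))
  inner <- function(j) ((j - 1L) %% n_c) + 1L
  outer_ <- function(j) n_c + ((j - 1L) %% n_c) + 1L
  faces <- list()
  for (j in seq_len(n_c)) {
    faces[[length(faces) + 1L]] <- c(inner(j), outer_(j), outer_(j + 1L))
    faces[[length(faces) + 1L]] <- c(inner(j), outer_(j + 1L), inner(j + 1L))
  }
  trimesh(verts, do.call(rbind, faces), name = "annulus")
}

# Closed UV sphere of radius r centred at the origin.
sphere_mesh <- function(n_lat = 12L, n_lon = 16L, r = 0.05) {
  lat <- seq(0, pi, length.out = n_lat + 2L)[2:(n_lat + 1L)]
  lon <- (seq_len(n_lon) - 1L) / n_lon * 2 * pi
  verts <- do.call(rbind, lapply(lat, function(ph) {
    cbind(r * sin(ph) * cos(lon), r * sin(ph) * sin(lon), r * cos(ph))
  }))
  vid <- function(k, j) (k - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  top <- nrow(verts) + 1L
  bot <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, r), c(0, 0, -r))
  faces <- list()
  for (k in seq_len(n_lat - 1L)) {
    for (j in seq_len(n_lon)) {
      faces[[length(faces) + 1L]] <- c(vid(k, j), vid(k, j + 1L), vid(k + 1L, j + 1L))
      faces[[length(faces) + 1L]] <- c(vid(k, j), vid(k + 1L, j + 1L), vid(k + 1L, j))
    }
  }
  for (j in seq_len(n_lon)) {
    faces[[length(faces) + 1L]] <- c(top, vid(1L, j + 1L), vid(1L, j))
    faces[[length(faces) + 1L]] <- c(bot, vid(n_lat, j), vid(n_lat, j + 1L))
  }
  trimesh(verts, do.call(rbind, faces), name = "sphere")
}

# Random star-shaped simple polygon with a guaranteed interior disk of
# radius 0.3 around the origin, plus a random point inside that disk.
random_polygon_case <- function() {
  n <- sample(8:16, 1L)
  ang <- 2 * pi * (seq_len(n) + runif(n, -0.3, 0.3)) / n
  rad <- runif(n, 0.9, 1.1)
  poly <- cbind(rad * cos(ang), rad * sin(ang))
  th <- runif(1L, 0, 2 * pi)
  rr <- runif(1L, 0, 0.3)
  list(polygon = poly, point = c(rr * cos(th), rr * sin(th)))
}

# Unit-cube OBJ text (8 vertices, 12 faces).
unit_cube_obj <- function(path) {
  v <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  writeLines(c(sprintf("v %g %g %g", v$x, v$y, v$z),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  path
}

# Dense quadratic-program oracle for fibre smoothing: minimise
# sum (q - p)^2 + lam * sum (second differences)^2 with fixed endpoints,
# solved through the full KKT stationarity system with a generic dense
# solver (independent of the package's partitioned banded solve).
smooth_qp_oracle <- function(p, lam) {
  np <- nrow(p)
  D <- matrix(0, np - 2L, np)
  for (k in seq_len(np - 2L)) D[k, k:(k + 2L)] <- c(1, -2, 1)
  A <- diag(np) + lam * t(D) %*% D
  N <- diag(np)[, 2:(np - 1L), drop = FALSE]   # basis of free coordinates
  out <- p
  for (j in seq_len(ncol(p))) {
    # stationarity: N' (q - p + lam D'D q) = 0 with q = p + N z
    M <- t(N) %*% A %*% N
    b <- t(N) %*% (p[, j] - A %*% p[, j])
    z <- qr.solve(M, b)
    out[, j] <- p[, j] + N %*% z
  }
  out
}
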