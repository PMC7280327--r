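# Small internal geometry helpers shared across modules.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

row_norms <- function(m) sqrt(rowSums(m * m))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# Any unit vector perpendicular to u.
perp_vector <- function(u) {
  u <- normalize(u)
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  normalize(cross3(u, ref))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Population standard deviation (divides by N, not N-1).
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

unit_scale <- function(units) {
  scale <- c(m = 1, mm = 1e-3, cm = 1e-2)
  if (!units %in% names(scale)) {
    stopf("unknown units '%s' (expected one of %s)", units,
          paste(names(scale), collapse = ", "))
  }
  unname(scale[units])
}
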