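# Attachment projection/removal, the full decomposition pipeline, endpoint
# connection and fibre smoothing.

test_that("attachment projection finds the tube caps", {
  tube <- make_tube_muscle(tube_spec(n_circumferential = 16L, n_axial = 8L))
  reg <- project_attachment(tube$mesh, tube$origin)
  cent <- muscledecomp:::face_centroids(tube$mesh)
  # every enclosed face lies on the z = 0 cap
  expect_lt(max(abs(cent[reg$faces, 3L])), 1e-9)
  expect_equal(length(reg$faces), 16L)

  # landmarks offset 1 mm below the cap project to the same region
  off <- tube$origin
  off$landmarks <- sweep(off$landmarks, 2L, c(0, 0, 1e-3))
  reg2 <- project_attachment(tube$mesh, off)
  expect_setequal(reg2$faces, reg$faces)
})

test_that("landmarks beyond the capture distance are rejected by name", {
  tube <- make_tube_muscle(tube_spec(n_circumferential = 16L, n_axial = 8L))
  far <- tube$origin
  far$landmarks[3L, ] <- far$landmarks[3L, ] + c(0, 0, -0.1)
  expect_error(project_attachment(tube$mesh, far, capture = 0.02),
               "landmark 3")
})

test_that("removing caps opens the expected boundary loops", {
  tube <- make_tube_muscle(tube_spec(n_circumferential = 16L, n_axial = 8L))
  reg_o <- project_attachment(tube$mesh, tube$origin)
  reg_i <- project_attachment(tube$mesh, tube$insertion)
  one <- remove_region(tube$mesh, reg_o)
  expect_length(boundary_loops(one), 1L)
  both <- remove_region(tube$mesh, sort(c(reg_o$faces, reg_i$faces)))
  expect_length(boundary_loops(both), 2L)
})

test_that("non simply connected regions are rejected", {
  tube <- make_tube_muscle(tube_spec(n_circumferential = 16L, n_axial = 8L))
  # an annular band of side-wall faces (one full ring around the tube)
  cent <- muscledecomp:::face_centroids(tube$mesh)
  band <- which(cent[, 3L] > 0.08 & cent[, 3L] < 0.12)
  expect_error(remove_region(tube$mesh, band), "simply connected")
})

test_that("straight-cylinder decomposition is accurate and deterministic", {
  tube <- make_tube_muscle()
  H <- 0.2
  fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                          n_fibers = 25L, n_segments = 10L)
  expect_equal(fib$n_fibers, 25L)
  expect_equal(fib$n_points, 11L)
  len <- fiber_lengths(fib)
  expect_lt(max(abs(len - H)) / H, 0.02)
  # interior points monotone along the field direction (z)
  expect_true(all(apply(fib$points[, , 3L], 1L, function(z) all(diff(z) > 0))))
  # fibres stay inside the tube (2% radial slack)
  rad <- sqrt(fib$points[, , 1L]^2 + fib$points[, , 2L]^2)
  expect_lt(max(rad), 0.03 * 1.02)
  # determinism: a second run is bit-identical
  fib2 <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                           n_fibers = 25L, n_segments = 10L)
  expect_identical(fib$points, fib2$points)
})

test_that("a single fibre tracks the cylinder axis", {
  tube <- make_tube_muscle()
  fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                          n_fibers = 1L, n_segments = 8L)
  rad <- sqrt(fib$points[1L, , 1L]^2 + fib$points[1L, , 2L]^2)
  expect_lt(max(rad), 0.01 * 0.2)   # within 1% of height from the axis
})

test_that("bent-tube fibre lengths match analytic arc lengths", {
  R <- 0.15
  k <- 0.5522847498            # cubic Bezier circle-arc coefficient
  ctrl <- rbind(c(R, 0, 0), c(R, 0, k * R), c(k * R, 0, R), c(0, 0, R))
  spec <- tube_spec(centerline = ctrl, radius = 0.02,
                    n_circumferential = 24L, n_axial = 16L)
  tube <- make_tube_muscle(spec)
  fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                          n_fibers = 16L, n_segments = 12L)
  len <- fiber_lengths(fib)
  # each fibre's arc radius is its mean distance from the bend axis (y axis)
  rho <- rowMeans(sqrt(fib$points[, , 1L]^2 + fib$points[, , 3L]^2))
  analytic <- rho * pi / 2
  expect_lt(max(abs(len - analytic) / analytic), 0.05)
})

test_that("endpoint connection lands on the attachment areas", {
  tube <- make_tube_muscle()
  fib1 <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                           n_fibers = 1L, n_segments = 8L)
  # centred single fibre: endpoints at the cap centroids
  expect_lt(vnorm_test(fib1$points[1L, 1L, ] - c(0, 0, 0)), 1e-6 + 2e-4)
  expect_lt(vnorm_test(fib1$points[1L, fib1$n_points, ] - c(0, 0, 0.2)),
            1e-6 + 2e-4)

  fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                          n_fibers = 36L, n_segments = 8L)
  starts <- fib$points[, 1L, ]
  expect_equal(nrow(unique(starts)), 36L)          # pairwise distinct
  expect_lt(vnorm_test(colMeans(starts) - c(0, 0, 0)), 0.05 * 0.03)
  expect_lt(max(abs(starts[, 3L])), 1e-6)          # on the cap plane
})

test_that("degenerate attachment outlines are rejected", {
  tube <- make_tube_muscle(tube_spec(n_circumferential = 12L, n_axial = 6L))
  fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                          n_fibers = 4L, n_segments = 5L)
  bad <- attachment_area("origin", "parent_bone",
                         cbind(seq(0, 1, length.out = 5L), 0, 0))
  attr(fib, "template") <- make_parallel_template(4L)
  expect_error(connect_attachments(fib, bad, tube$insertion), "degenerate")
})

test_that("fibre smoothing: identity, invariance and the QP oracle", {
  np <- 10L
  straight <- array(0, dim = c(1L, np, 3L))
  straight[1L, , 1L] <- seq(0, 1, length.out = np)
  fib <- fiber_set(straight)
  expect_identical(smooth_fibers(fib, 0), fib)
  # collinear equispaced fibre is a fixed point for any lam
  sm <- smooth_fibers(fib, 5)
  expect_equal(sm$points, fib$points, tolerance = 1e-12)

  set.seed(77)
  for (rep in 1:5) {
    zig <- cbind(seq(0, 0.2, length.out = np),
                 stats::rnorm(np, sd = 0.01),
                 stats::rnorm(np, sd = 0.01))
    f <- fiber_set(array(zig, dim = c(1L, np, 3L)))
    got <- smooth_fibers(f, 1)$points[1L, , ]
    want <- smooth_qp_oracle(zig, 1)
    expect_lt(max(abs(got - want)), 1e-10)
    # endpoints stay fixed
    expect_identical(got[c(1L, np), ], zig[c(1L, np), ])
  }
})

test_that("fiber sets round-trip through JSON and CSV", {
  tube <- make_tube_muscle(tube_spec(n_circumferential = 12L, n_axial = 6L))
  fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                          n_fibers = 4L, n_segments = 5L)
  jp <- withr::local_tempfile(fileext = ".json")
  write_fiber_set(fib, jp)
  back <- read_fiber_set(jp)
  expect_equal(back$points, fib$points, tolerance = 1e-12)
  expect_equal(back$n_fibers, fib$n_fibers)
  cp <- withr::local_tempfile(fileext = ".csv")
  write_fiber_csv(fib, cp)
  df <- utils::read.csv(cp)
  expect_equal(nrow(df), 4L * 6L)
  expect_equal(df$x[1L], fib$points[1L, 1L, 1L])
})
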