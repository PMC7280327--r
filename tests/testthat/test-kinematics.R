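# Blending weights, bone binding, pose transforms and fibre updates.

test_that("weight function satisfies its boundary conditions and values", {
  for (a in muscle_weight_params()) {
    w0 <- weight_function(a, 0)
    w1 <- weight_function(a, 1)
    expect_identical(w0$w1, 1)
    expect_identical(w1$w1, 0)
    expect_equal(w0$w1 + w0$w2, 1)
  }
  expect_equal(weight_function(0, 0.5)$w1, 0.5)
  expect_equal(weight_function(-0.042, 0.5)$w1, 0.5105)
  expect_equal(weight_function(-1, 0.5)$w1, 0.75)
  expect_error(weight_function(0, 1.5), "\\[0, 1\\]")
})

test_that("bone assignment binds every point to both toy bones", {
  skel <- make_two_bone_skeleton()
  tube <- make_tube_muscle(tube_spec(n_circumferential = 12L, n_axial = 6L))
  fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                          n_fibers = 4L, n_segments = 5L)
  fib <- assign_bones(fib, skel, a = -0.042, origin_bone = "parent_bone")
  expect_setequal(unique(as.vector(fib$bindings$bones)),
                  c("parent_bone", "child_bone"))
  # first point fully on the origin bone, last fully on the other
  expect_true(all(fib$bindings$w[, 1L, 1L] == 1))
  expect_true(all(fib$bindings$w[, fib$n_points, 1L] == 0))
  # weights sum to one everywhere
  expect_equal(max(abs(rowSums(matrix(fib$bindings$w, ncol = 2L)) - 1)), 0)
  # inference agrees with the declaration for this geometry
  auto <- assign_bones(fib, skel, a = -0.042)
  expect_identical(auto$bindings$bones, fib$bindings$bones)
  expect_error(assign_bones(fib, skeleton(skel$bones["parent_bone"],
                                          c(0, 0, 0), "parent_bone",
                                          "parent_bone")), "two bones")
})

test_that("pose transforms: identity at rest, fixed joint centre", {
  skel <- make_two_bone_skeleton()
  tf0 <- pose_transforms(skel, joint_pose())
  expect_equal(tf0$parent_bone$R, diag(3))
  expect_equal(tf0$child_bone$R, diag(3))
  expect_equal(tf0$child_bone$t, c(0, 0, 0))
  set.seed(9)
  for (i in 1:10) {
    pose <- joint_pose(flexion = stats::runif(1, -10, 60),
                       adduction = stats::runif(1, -40, 40),
                       rotation = stats::runif(1, -30, 30))
    tf <- pose_transforms(skel, pose)
    cen <- skel$joint$center
    expect_lt(vnorm_test(as.vector(
      muscledecomp:::apply_transform(tf$child_bone, cen)) - cen), 1e-12)
  }
  expect_error(pose_transforms(skel, joint_pose(flexion = 90)), "range")
})

test_that("pure flexion rotates child points about z analytically", {
  skel <- make_two_bone_skeleton(center = c(0, 0, 0),
                                 coord_ranges = list(flexion = c(-180, 180)))
  tf <- pose_transforms(skel, joint_pose(flexion = 90))
  img <- muscledecomp:::apply_transform(tf$child_bone, c(0, -0.1, 0))
  expect_equal(as.vector(img), c(0.1, 0, 0), tolerance = 1e-12)
})

test_that("fibre update is an affine blend with rigid endpoints", {
  skel <- make_two_bone_skeleton()
  tube <- make_tube_muscle(tube_spec(n_circumferential = 12L, n_axial = 8L))
  fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                          n_fibers = 9L, n_segments = 6L)
  expect_error(update_fibers(fib, pose_transforms(skel, joint_pose())),
               "bindings")
  fib <- assign_bones(fib, skel, a = -0.042, origin_bone = "parent_bone")

  # identity pose returns the rest geometry exactly
  posed0 <- update_fibers(fib, pose_transforms(skel, joint_pose()))
  expect_equal(max(abs(posed0$points - fib$points)), 0)

  # both bones translated by the same vector: pure translation of all points
  d <- c(0.01, -0.02, 0.03)
  tfd <- list(parent_bone = rigid_transform(diag(3), d),
              child_bone = rigid_transform(diag(3), d))
  posed_d <- update_fibers(fib, tfd)
  expect_equal(posed_d$points[, , 1L], fib$points[, , 1L] + d[1L])
  expect_equal(posed_d$points[, , 3L], fib$points[, , 3L] + d[3L])

  # under a real pose every blended point lies between its two rigid images
  tf <- pose_transforms(skel, joint_pose(flexion = 35, adduction = -10))
  posed <- update_fibers(fib, tf)
  pts <- matrix(aperm(fib$points, c(2L, 1L, 3L)), ncol = 3L)
  img_p <- muscledecomp:::apply_transform(tf$parent_bone, pts)
  img_c <- muscledecomp:::apply_transform(tf$child_bone, pts)
  out <- matrix(aperm(posed$points, c(2L, 1L, 3L)), ncol = 3L)
  w1 <- as.vector(t(fib$bindings$w[, , 1L]))
  recon <- w1 * img_p + (1 - w1) * img_c
  expect_lt(max(abs(out - recon)), 1e-12)

  # statelessness: rest fibres unchanged by posing
  expect_identical(fib$points,
                   assign_bones(fib, skel, a = -0.042,
                                origin_bone = "parent_bone")$points)
})

test_that("endpoints move rigidly with their bones across the sweep", {
  skel <- make_two_bone_skeleton()
  tube <- make_tube_muscle(tube_spec(n_circumferential = 12L, n_axial = 8L))
  fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                          n_fibers = 4L, n_segments = 6L)
  fib <- assign_bones(fib, skel, a = -0.024, origin_bone = "parent_bone")
  np <- fib$n_points
  for (th in seq(-10, 60, by = 10)) {
    tf <- pose_transforms(skel, joint_pose(flexion = th))
    posed <- update_fibers(fib, tf)
    first <- muscledecomp:::apply_transform(tf$parent_bone,
                                            matrix(fib$points[, 1L, ], ncol = 3L))
    last <- muscledecomp:::apply_transform(tf$child_bone,
                                           matrix(fib$points[, np, ], ncol = 3L))
    expect_lt(max(abs(posed$points[, 1L, ] - first)), 1e-12)
    expect_lt(max(abs(posed$points[, np, ] - last)), 1e-12)
  }
})
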