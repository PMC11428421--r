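# Rigid-transform algebra and the SVD paired-point solve.

test_that("quaternion constructors normalize and canonicalize", {
  T1 <- rigid_transform(c(2, 0, 0, 0), c(1, 2, 3))
  expect_equal(sum(T1$q^2), 1, tolerance = 1e-12)
  # antipodal quaternions canonicalize to w >= 0
  T2 <- rigid_transform(-c(0.5, 0.5, 0.5, 0.5), c(0, 0, 0))
  expect_gte(T2$q[1], 0)
  expect_error(rigid_transform(c(0, 0, 0, 0)), "zero-norm")
  R <- quat_to_matrix(T2$q)
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_equal(quat_normalize(matrix_to_quat(R)), T2$q, tolerance = 1e-9)
})

test_that("svd solve reproduces identity and pure translation exactly", {
  P <- tetrahedron()
  T_id <- svd_paired_point_register(P, P)
  expect_transforms_equal(T_id, rt_identity())
  T_tr <- svd_paired_point_register(P, sweep(P, 2, c(5, 0, 0), "+"))
  expect_equal(T_tr$q, c(1, 0, 0, 0), tolerance = 1e-9)
  expect_equal(T_tr$t, c(5, 0, 0), tolerance = 1e-9)
  expect_equal(paired_rms(rt_apply(T_id, P), P), 0, tolerance = 1e-12)
})

test_that("svd solve recovers a constructed rotation + shift to 1e-9", {
  q90 <- euler_to_quat(c(90, 0, 0)) # 90 degrees about z
  T_true <- rigid_transform(q90, c(1, 2, 3))
  P <- tetrahedron()
  T_hat <- svd_paired_point_register(P, rt_apply(T_true, P))
  expect_transforms_equal(T_hat, T_true, tol = 1e-9)
})

test_that("svd solve exactly recovers random rigid transforms", {
  set.seed(11)
  for (i in 1:20) {
    T_true <- random_rigid_transform(100)
    P <- matrix(rnorm(24, sd = 40), ncol = 3)
    T_hat <- svd_paired_point_register(P, rt_apply(T_true, P))
    expect_transforms_equal(T_hat, T_true, tol = 1e-8)
  }
})

test_that("svd solve beats 10,000 random rigid transforms in residual", {
  set.seed(7)
  P <- tetrahedron() * 10
  Q <- rt_apply(rigid_transform(random_quaternion(), c(3, -2, 1)), P) +
    matrix(rnorm(12, sd = 0.5), ncol = 3) # noisy correspondence
  best <- svd_paired_point_register(P, Q)
  mse_best <- paired_mse(rt_apply(best, P), Q)
  mse_rand <- replicate(10000, {
    paired_mse(rt_apply(random_rigid_transform(10), P), Q)
  })
  expect_true(all(mse_best <= mse_rand + 1e-12))
})

test_that("near-planar configurations never yield a reflection", {
  set.seed(3)
  for (i in 1:20) {
    P <- cbind(matrix(rnorm(20, sd = 30), ncol = 2), rnorm(10, sd = 1e-4))
    T_true <- random_rigid_transform(50)
    # add noise that might tempt the solve toward a reflection
    Q <- rt_apply(T_true, P) + matrix(rnorm(30, sd = 3), ncol = 3)
    T_hat <- svd_paired_point_register(P, Q)
    expect_equal(det(quat_to_matrix(T_hat$q)), 1, tolerance = 1e-9)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  P <- tetrahedron()
  expect_error(svd_paired_point_register(P, P[1:3, ]), "correspondence")
  expect_error(svd_paired_point_register(P[1:2, ], P[1:2, ]),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(svd_paired_point_register(line, line), "collinear")
})

test_that("composition, inversion and application satisfy group laws", {
  set.seed(5)
  A <- random_rigid_transform(50)
  B <- random_rigid_transform(50)
  C <- random_rigid_transform(50)
  P <- matrix(rnorm(30, sd = 20), ncol = 3)

  expect_transforms_equal(rt_compose(A, rt_identity()), A, tol = 1e-12)
  expect_transforms_equal(rt_compose(A, rt_invert(A)), rt_identity(),
                          tol = 1e-9)
  expect_transforms_equal(rt_invert(rt_identity()), rt_identity())

  # compose-then-apply equals sequential application
  expect_equal(rt_apply(rt_compose(A, B), P), rt_apply(A, rt_apply(B, P)),
               tolerance = 1e-12)
  # associativity under pointwise application
  left <- rt_apply(rt_compose(rt_compose(A, B), C), P)
  right <- rt_apply(rt_compose(A, rt_compose(B, C)), P)
  expect_equal(left, right, tolerance = 1e-12)
})

test_that("rigid application preserves pairwise distances", {
  set.seed(9)
  P <- matrix(rnorm(60, sd = 30), ncol = 3)
  T1 <- random_rigid_transform(200)
  expect_equal(as.matrix(dist(rt_apply(T1, P))), as.matrix(dist(P)),
               tolerance = 1e-9)
  expect_equal(rt_apply(rt_identity(), P), P)
  expect_equal(rt_apply(rigid_transform(translation = c(0, 0, 1)), c(0, 0, 0)),
               c(0, 0, 1))
})

test_that("euler conversions follow the intrinsic z-y-x convention", {
  expect_equal(euler_to_quat(c(0, 0, 0)), c(1, 0, 0, 0))
  # yaw 90: x-axis maps to y-axis
  expect_equal(rt_apply(rigid_transform(euler_to_quat(c(90, 0, 0))),
                        c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  # pitch 90: x-axis maps to -z
  expect_equal(rt_apply(rigid_transform(euler_to_quat(c(0, 90, 0))),
                        c(1, 0, 0)),
               c(0, 0, -1), tolerance = 1e-12)
  # roll 90: y-axis maps to z
  expect_equal(rt_apply(rigid_transform(euler_to_quat(c(0, 0, 90))),
                        c(0, 1, 0)),
               c(0, 0, 1), tolerance = 1e-12)
})

test_that("quat -> euler -> quat round-trips 1000 random rotations", {
  set.seed(13)
  p <- c(1, 2, 3)
  worst <- 0
  for (i in 1:1000) {
    q <- random_quaternion()
    q2 <- euler_to_quat(quat_to_euler(q))
    worst <- max(worst, max(abs(rt_apply(rigid_transform(q), p) -
                                  rt_apply(rigid_transform(q2), p))))
  }
  expect_lt(worst, 1e-6)
})

test_that("homogeneous matrix and JSON round trips preserve the transform", {
  set.seed(17)
  T1 <- random_rigid_transform(80)
  M <- as.matrix(T1)
  expect_equal(dim(M), c(4, 4))
  expect_equal(M[4, ], c(0, 0, 0, 1))
  expect_transforms_equal(rt_from_matrix(M), T1, tol = 1e-12)
  expect_transforms_equal(rt_from_json(rt_to_json(T1)), T1, tol = 1e-12)
})
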