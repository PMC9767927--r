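test_that("elemental rotations are orthonormal right-handed rotations", {
  expect_equal(rot_z(0), diag(3))
  expect_equal(rot_x(pi / 2) %*% c(0, 1, 0), cbind(c(0, 0, 1)))
  set.seed(11)
  for (a in runif(20, -10, 10)) {
    for (R in list(rot_x(a), rot_y(a), rot_z(a))) {
      expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
  }
  a <- runif(50, -5, 5); b <- runif(50, -5, 5)
  for (i in seq_along(a))
    expect_equal(rot_z(a[i]) %*% rot_z(b[i]), rot_z(a[i] + b[i]),
                 tolerance = 1e-12)
})

test_that("helix centre starts at the top and advances one pitch per orbit", {
  hp <- helix_params(v = 0.5, omega_helix = 2 * pi * 0.5 / 0.7, h = 35)
  expect_equal(helix_center(0, hp)[1, ], c(x = 0, y = 0, z = 35))
  T1 <- 2 * pi / hp$omega_helix
  p1 <- helix_center(T1, hp)[1, ]
  expect_equal(unname(p1["x"]), 2 * pi * hp$v / hp$omega_helix,
               tolerance = 1e-12)   # pitch = 2 pi v / omega
  expect_equal(unname(p1[c("y", "z")]), c(0, 35), tolerance = 1e-9)
  t <- seq(0, 3, by = 0.01)
  ctr <- helix_center(t, hp)
  expect_equal(ctr[, "y"]^2 + ctr[, "z"]^2, rep(35^2, length(t)),
               tolerance = 1e-9)
})

test_that("closed-form pose matches the rotation-matrix product and stays symmetric", {
  set.seed(42)
  for (rep in 1:25) {
    hp <- helix_params(v = runif(1, 0.1, 1), omega_helix = runif(1, -8, 8),
                       h = runif(1, 0, 100))
    yr <- yaw_roll_params(runif(1, -8, 8), runif(1, -8, 8), runif(1, 0, pi))
    geom <- rod_geometry()
    t <- runif(8, 0, 5)
    a <- rod_pose(t, hp, yr, geom)
    b <- rod_pose_matrix(t, hp, yr, geom)
    expect_equal(a$tip, b$tip, tolerance = 1e-12)
    expect_equal(a$end, b$end, tolerance = 1e-12)
    expect_equal(a$tip + a$end, 2 * a$center, tolerance = 1e-12)
  }
})

test_that("rod starts along the microtubule axis and its centre ignores yaw/roll", {
  hp <- helix_params(0.5, 4.5, 35)
  geom <- rod_geometry()
  p <- rod_pose(0, hp, yaw_roll_params(4.5, -2.25, 0), geom)
  expect_equal(as.numeric(p$tip[1, ] - p$end[1, ]), c(2 * geom$r, 0, 0))
  t <- seq(0, 2, by = 0.1)
  c1 <- rod_pose(t, hp, yaw_roll_params(4.5, -2.25, 0.3), geom)$center
  c2 <- rod_pose(t, hp, yaw_roll_params(-1.0, 3.0, 1.2), geom)$center
  expect_equal(c1, c2)
})

test_that("projected angle reduces to phi at t = 0 and collapses at quarter roll", {
  yr <- yaw_roll_params(2 * pi, -pi, phi = 0.7)
  expect_equal(projected_angle(0, yr)$angle, 0.7)
  # roll angle pi/2 with yaw angle != pi/2: projection lies along X
  t_quarter <- 0.25
  pa <- projected_angle(t_quarter, yr)
  expect_true(pa$defined)
  expect_lt(min(pa$angle, pi - pa$angle), 1e-9)   # 0 modulo the half-turn
})

test_that("coupled rotation turns the rod a half-turn per orbit and mirrors under yaw sign", {
  w <- 2 * pi
  t <- seq(0, 1, length.out = 1001)
  for (ys in c(-1, 1)) {
    yr <- yaw_roll_params(w, ys * w / 2, phi = 0.3)
    u <- unwrap_angle(projected_angle(t, yr)$angle)
    expect_equal(abs(u[length(u)] - u[1]), pi, tolerance = 1e-6)
  }
  # sign flip is a time reversal of the series (mirror image trace)
  a_p <- projected_angle(-t, yaw_roll_params(w, w / 2, 0.3))$angle
  a_m <- projected_angle(t, yaw_roll_params(w, -w / 2, 0.3))$angle
  expect_equal(a_p, a_m, tolerance = 1e-12)
  # and flips the sense of the net rotation
  u_p <- unwrap_angle(projected_angle(t, yaw_roll_params(w, w / 2, 0.3))$angle)
  u_m <- unwrap_angle(a_m)
  expect_equal(u_p[length(t)] - u_p[1], -(u_m[length(t)] - u_m[1]),
               tolerance = 1e-9)
})

test_that("zero yaw gives a periodic, never-unidirectional angle; zero roll keeps it constant", {
  w <- 2 * pi
  t <- seq(0, 3, length.out = 3001)
  yr <- yaw_roll_params(omega_roll = w, omega_yaw = 0, phi = 0.5)
  u <- unwrap_angle(projected_angle(t, yr)$angle)
  # periodic with the helix period
  expect_equal(u[t %% 1 < 1e-9], rep(u[1], 4), tolerance = 1e-9)
  # net rotation per period far from a half-turn
  expect_lt(max(abs(u - u[1])), pi / 2)
  still <- projected_angle(t, yaw_roll_params(0, 0, 0.5))$angle
  expect_equal(still, rep(0.5, length(t)))
})

test_that("initial phase selects counterclockwise, clockwise or oscillatory patterns", {
  # clockwise yawing
  expect_identical(classify_pattern(0, yaw_sign = -1), "counterclockwise")
  expect_identical(classify_pattern(pi / 2, yaw_sign = -1), "clockwise")
  expect_identical(classify_pattern(pi / 4, yaw_sign = -1), "oscillatory")
  expect_identical(classify_pattern(3 * pi / 4, yaw_sign = -1), "oscillatory")
  # counterclockwise yawing mirrors the map
  expect_identical(classify_pattern(0, yaw_sign = 1), "clockwise")
  expect_identical(classify_pattern(pi / 2, yaw_sign = 1), "counterclockwise")
})

test_that("unwrap_angle removes half-turn wraps and bridges NAs", {
  th <- seq(0, 3 * pi, length.out = 200)
  expect_equal(unwrap_angle(th %% pi), th, tolerance = 1e-9)
  x <- c(0.1, NA, 0.2)
  expect_equal(unwrap_angle(x), c(0.1, NA, 0.2))
})
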