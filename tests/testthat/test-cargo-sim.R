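test_that("initial state binds every motor near its joint", {
  p <- sim_params(seed = 1)
  s <- cargo_init(p)
  expect_equal(nrow(s$joints), 13)
  expect_true(all(s$bound))
  # nearest-site rounding bounds the initial spring energy
  d <- s$motor_pos - s$joints
  energy <- p$k / 2 * rowSums(d^2)
  expect_true(all(energy <= p$k / 2 * 2 * 0.5^2 + 1e-12))
  expect_identical(cargo_init(p), s)
})

test_that("force balance with one bound motor zeroes its spring", {
  p <- sim_params(seed = 1)
  s <- cargo_init(p)
  s$bound[2:13] <- FALSE
  s$motor_pos[1, ] <- c(5, -3)
  s <- solve_balance(s, p, n_step = 0)
  jw <- s$pos + c(cos(s$theta) * s$joints[1, 1] - sin(s$theta) * s$joints[1, 2],
                  sin(s$theta) * s$joints[1, 1] + cos(s$theta) * s$joints[1, 2])
  expect_equal(unname(s$motor_pos[1, ] - jw), c(0, 0), tolerance = 1e-12)
})

test_that("an already balanced two-motor configuration does not move", {
  p <- sim_params(n_motors = 2, joint_radius = 1, seed = 1)
  s <- cargo_init(p)
  # joints at (1,0) and (-1,0); equal and opposite extensions about the centre
  s$motor_pos <- rbind(c(1, 0.3), c(-1, -0.3))
  s0 <- solve_balance(s, p, n_step = 0)
  # net force is zero and net moment zero: theta solves to the same pose
  expect_equal(s0$pos, c(0, 0), tolerance = 1e-9)
  expect_equal(s0$residual, 0, tolerance = 1e-9)
})

test_that("random bound configurations satisfy both balance equations to 1e-9", {
  set.seed(17)
  p <- sim_params(n_motors = 5, t_step = -3, joint_radius = 2, seed = 1)
  for (rep in 1:40) {
    s <- cargo_init(p)
    s$bound <- runif(5) < 0.8
    if (!any(s$bound)) s$bound[1] <- TRUE
    s$motor_pos <- s$motor_pos + matrix(round(runif(10, -2, 2)), 5, 2)
    s$theta <- runif(1, -0.5, 0.5)
    n_step <- sample(0:1, 1)
    s <- solve_balance(s, p, n_step = n_step)
    b <- s$bound
    jw <- gnrtrack:::.joint_world(s$pos, s$theta, s$joints)[b, , drop = FALSE]
    d <- s$motor_pos[b, , drop = FALSE] - jw
    expect_lt(max(abs(colSums(p$k * d))), 1e-9)
    if (sum(b) > 1 && !s$saturated) {
      a <- s$joints[b, , drop = FALSE]
      ct <- cos(s$theta); st <- sin(s$theta)
      bl <- sweep(a, 2, colMeans(a))
      lp <- cbind(bl[, 1] * ct - bl[, 2] * st, bl[, 1] * st + bl[, 2] * ct)
      moment <- sum(p$k * (lp[, 1] * d[, 2] - lp[, 2] * d[, 1]))
      expect_equal(moment, p$t_step * n_step, tolerance = 1e-9)
    }
  }
})

test_that("zero diffusion quenches stepping and transport", {
  # without diffusion the barrier test sees only the tiny rotational
  # re-equilibration wiggles of the pose, so stepping all but vanishes
  r <- cargo_run(sim_params(sigma = 0, seed = 3), 2000)
  r1 <- cargo_run(sim_params(seed = 3), 2000)
  expect_lt(sum(r$counts), 0.15 * sum(r1$counts))
  expect_lt(abs(r$summary$net_y), 1)
})

test_that("symmetric barriers produce no systematic drift", {
  p0 <- sim_params(alpha_x = 0.5, alpha_y = 0.5, seed = 1)
  drift <- t(vapply(1:24, function(s) {
    p <- p0; p$seed <- s
    r <- cargo_run(p, 2500)
    c(r$summary$net_x, r$summary$net_y)
  }, c(0, 0)))
  for (j in 1:2) {
    sem <- sd(drift[, j]) / sqrt(nrow(drift))
    expect_lt(abs(mean(drift[, j])), 3 * sem + 1e-9)
  }
})

test_that("the default barriers bias forward stepping far above leftward", {
  r <- cargo_run(sim_params(seed = 5), 15000)
  nf <- r$counts[["forward"]] - r$counts[["backward"]]
  nl <- r$counts[["left"]] - r$counts[["right"]]
  expect_gt(nf, 5 * nl)
  expect_gt(nl, 0)
  sr <- step_ratio(r)
  expect_equal(sr$forward, 100)
  expect_equal(sr$leftward, 100 * nl / nf)
})

test_that("identical seeds give bit-identical runs", {
  p <- sim_params(seed = 9)
  r1 <- cargo_run(p, 1500)
  r2 <- cargo_run(p, 1500)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$counts, r2$counts)
  p$seed <- 10L
  expect_false(identical(cargo_run(p, 1500)$counts, r1$counts))
})

test_that("mirroring the off-axis asymmetry mirrors the lateral drift", {
  y_at <- function(ay) {
    mean(vapply(1:8, function(s)
      cargo_run(sim_params(alpha_y = ay, seed = s), 4000)$summary$net_y, 0))
  }
  yl <- y_at(0.58); yr <- y_at(0.42)
  expect_lt(yl, 0)
  expect_gt(yr, 0)
})

test_that("without torque the cargo accumulates no systematic rotation", {
  th <- vapply(1:10, function(s)
    cargo_run(sim_params(seed = s), 4000)$summary$net_theta, 0)
  sem <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th)), 3 * sem + 1e-9)
})

test_that("balance residuals hold after every tick of a full run", {
  r <- cargo_run(sim_params(seed = 12), 4000, record_residuals = TRUE)
  expect_lt(max(r$trace$residual), 1e-9)
  expect_equal(r$n_saturated, 0L)
})

test_that("step torque drives net clockwise pose rotation", {
  # the locked-in winding is weak against its run-to-run wander: pool seeds
  th <- vapply(1:8, function(s)
    cargo_run(sim_params(seed = s, t_step = -24), 15000)$summary$net_theta, 0)
  expect_lt(mean(th), 0)
})

test_that("a symmetric off-axis barrier yields a ~100:0 ratio and pitch conversion works", {
  runs <- lapply(1:6, function(s)
    cargo_run(sim_params(alpha_y = 0.5, seed = s), 8000))
  sr <- step_ratio(runs)
  expect_lt(abs(sr$leftward), 3)
  expect_equal(pitch_equivalent(list(leftward = 13)), 100 / 13 * 13 * 8 / 1000)
  expect_error(pitch_equivalent(list(leftward = -1)), "leftward")
  none <- runs[[1]]
  none$counts[] <- 0L
  expect_error(step_ratio(none), "forward")
})
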