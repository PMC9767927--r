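test_that("velocity fit is exact on a linear trace and unbiased under noise", {
  tr <- data.frame(t = seq(0, 5, by = 0.01))
  tr$x_um <- 0.5 * tr$t
  expect_equal(fit_velocity(tr), 0.5)
  set.seed(21)
  vs <- replicate(50, {
    tr$x_um <- 0.5 * tr$t + rnorm(nrow(tr), 0, 0.02)
    fit_velocity(tr)
  })
  expect_equal(mean(vs), 0.5, tolerance = 0.005)
  expect_error(fit_velocity(data.frame(t = 1:3, x_um = 1:3)), "frames")
})

test_that("velocity of a generated track matches the generator input", {
  tk <- ref_track(v = 0.51, duration = 4, noise = noise_spec(3, 10, 0))
  expect_equal(fit_velocity(tk$noisy), 0.51, tolerance = 0.02)
})

test_that("cycle detection finds sine periods and rejects monotone ramps", {
  t <- seq(0, 3.2, by = 0.002)
  cyc <- detect_cycles(sin(2 * pi * t), t, smooth_window = 1)
  expect_equal(nrow(cyc), 3)                 # three interior unit periods
  expect_equal(cyc$end_t - cyc$start_t, rep(1, 3), tolerance = 0.01)
  expect_equal(nrow(detect_cycles(t, t, 1)), 0)
})

test_that("cycle periods stay within 5% on noisy sines", {
  t <- seq(0, 6, by = 0.01)
  errs <- vapply(1:60, function(s) {
    set.seed(s)
    y <- sin(2 * pi * t) + rnorm(length(t), 0, 1 / 5)   # SNR 5 in sd
    cyc <- detect_cycles(y, t, smooth_window = 15)
    if (nrow(cyc) == 0) return(NA_real_)
    mean(cyc$end_t - cyc$start_t)
  }, 0)
  expect_lt(max(abs(errs - 1), na.rm = TRUE), 0.05)
})

test_that("helix and polarization pitches agree under the coupled model", {
  tk <- ref_track(phi = 0.9, duration = 6)
  tr <- with_angles(tk$noisy)
  hp <- helix_pitch(tr)
  pp <- polarization_pitch(tr)
  expect_equal(hp$mean, 0.7, tolerance = 0.02)
  expect_equal(pp$mean / hp$mean, 1, tolerance = 0.02)
  expect_gte(hp$n, 3)
  expect_true(all(hp$cycles$x_displacement_um > 0))
  # pitch identity: 2 pi v / omega
  gt <- ground_truth()
  expect_equal(hp$mean,
               2 * pi * gt$model$hp$v / abs(gt$model$hp$omega_helix),
               tolerance = 0.02)
})

test_that("doubling the yaw rate halves the polarization pitch", {
  w <- 2 * pi * 0.5 / 0.7
  gt <- ground_truth(model = motion_model(phi = 0.3, omega_yaw = -w),
                     duration = 6, seed = 1)
  tk <- gen_track(gt, noise_spec(0, 0, 0))
  tr <- with_angles(tk$noisy)
  expect_equal(polarization_pitch(tr)$mean / helix_pitch(tr)$mean, 0.5,
               tolerance = 0.03)
})

test_that("DOP-based cycles give the same polarization pitch", {
  tk <- ref_track(phi = 0.2, duration = 6)
  tr <- with_angles(tk$noisy)
  expect_equal(polarization_pitch(tr, signal = "dop")$mean,
               polarization_pitch(tr)$mean, tolerance = 0.05)
})

test_that("supertwist correction inverts the reciprocal pitch composition", {
  expect_equal(correct_pitch(0.7, Inf), 0.7)
  expect_equal(correct_pitch(0.7, -24.8), 1 / (1 / 0.7 + 1 / 24.8))
  expect_equal(correct_pitch(0.7, -24.8), 0.681, tolerance = 1e-3)
  # exact inverse of the forward composition
  p_motor <- 0.64
  for (pf in c(12, 13, 14)) {
    p_mt <- supertwist_pitch(pf)
    p_meas <- 1 / (1 / p_motor + 1 / p_mt)
    expect_equal(correct_pitch(p_meas, p_mt), p_motor, tolerance = 1e-12)
  }
  # sub-micrometre pitches move by less than the 1/(1 - |p|/|p_mt|) bound
  for (p in c(0.3, 0.7, 1)) for (pf in c(12, 13, 14)) {
    rel <- abs(correct_pitch(p, supertwist_pitch(pf)) - p) / p
    expect_lt(rel, 1 / (1 - 1 / 3.4) - 1 + 1e-9)   # worst case |p_mt| = 3.4
  }
  expect_error(correct_pitch(0.7, 0.7))
  expect_equal(supertwist_pitch(c(12, 13, 14)), c(-3.4, -24.8, 6.8))
  expect_error(supertwist_pitch(11), "protofilaments")
})

test_that("cross-correlation is Pearson-normalized with the signal period", {
  t <- seq(0, 4, by = 0.01)
  a <- sin(2 * pi * t)
  cc <- cross_correlation(a, a, max_lag = 150)
  expect_equal(cc$ccf[cc$lag == 0], 1, tolerance = 1e-9)
  expect_equal(cc$ccf[cc$lag == 100], 1, tolerance = 0.01)  # one period
  sh <- cross_correlation(a, cos(2 * pi * t), max_lag = 150)
  expect_equal(sh$ccf[sh$lag == 0], 0, tolerance = 1e-9)
  # cosine leads by a quarter period; peaks recur one period apart
  expect_equal(sh$ccf[sh$lag == -25], 1, tolerance = 0.01)
  expect_equal(sh$ccf[sh$lag == 75], 1, tolerance = 0.01)
  cst <- cross_correlation(a, rep(1, length(a)), 10)
  expect_true(all(is.na(cst$ccf)))
})

test_that("the Y-DOP cross-correlation of a track is periodic at the helix period", {
  tk <- ref_track(phi = 0.5, duration = 6, noise = noise_spec(3, 10, 0))
  cc <- cross_correlation(tk$noisy$y_um, tk$noisy$dop, max_lag = 200)
  # peaks separated by one helix period (0.7/0.5 s = 140 frames)
  pk <- cc$lag[cc$lag > 50 & cc$lag < 200][which.max(cc$ccf[cc$lag > 50 &
                                                              cc$lag < 200])]
  pk0 <- cc$lag[abs(cc$lag) <= 50][which.max(cc$ccf[abs(cc$lag) <= 50])]
  expect_equal(pk - pk0, 140, tolerance = 10)
})

test_that("the Pearson correlation sign recovers the yaw direction", {
  tr_cw <- with_angles(ref_track(phi = 0.7, yaw_sign = -1,
                                 noise = noise_spec(3, 10, 0))$noisy)
  yd <- yaw_direction(tr_cw)
  expect_lt(yd$pearson_r, 0)
  expect_identical(yd$direction, "cw")
  tr_ccw <- with_angles(ref_track(phi = 0.7, yaw_sign = 1,
                                  noise = noise_spec(3, 10, 0))$noisy)
  yd2 <- yaw_direction(tr_ccw)
  expect_gt(yd2$pearson_r, 0)
  expect_identical(yd2$direction, "ccw")
})

test_that("zero yaw leaves the direction undetermined across seeds", {
  dirs <- vapply(1:10, function(s) {
    gt <- ground_truth(model = motion_model(phi = 0.6, omega_yaw = 0),
                       duration = 6, seed = s)
    tr <- with_angles(gen_track(gt, noise_spec(3, 10, 0))$noisy)
    abs(yaw_direction(tr)$pearson_r)
  }, 0)
  expect_lt(median(dirs), 0.3)
})

test_that("the exact binomial direction test doubles the smaller tail", {
  expect_equal(binomial_direction_test(8, 13),
               2 * sum(choose(13, 8:13)) / 2^13)
  expect_equal(binomial_direction_test(8, 13), 0.581, tolerance = 1e-3)
  expect_equal(binomial_direction_test(13, 13), 2 / 8192)
  expect_equal(binomial_direction_test(5, 10), 1)
  # agrees with the central exact test at p = 1/2, where both are symmetric
  for (k in 0:13)
    expect_equal(binomial_direction_test(k, 13),
                 binom.test(k, 13, 0.5)$p.value, tolerance = 1e-12)
  expect_error(binomial_direction_test(1, 0))
})

test_that("Welch's test behaves at its limits and holds its size", {
  x <- c(1.2, 1.9, 2.4, 3.1)
  expect_equal(welch_test(x, x), 1)
  expect_lt(welch_test(rnorm(20, 0, 0.1), rnorm(20, 50, 0.1)), 1e-10)
  set.seed(31)
  rej <- mean(replicate(2000, {
    welch_test(rnorm(10), rnorm(10, 0, 2)) < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("analyze_track assembles the full per-track report", {
  tk <- ref_track(phi = 0.4, noise = noise_spec(3, 10, 0))
  rep <- analyze_track(tk$noisy, ref_cal())
  expect_s3_class(rep, "track_report")
  expect_equal(rep$velocity_um_s, 0.5, tolerance = 0.02)
  expect_equal(rep$polarization_pitch$mean / rep$helix_pitch$mean, 1,
               tolerance = 0.05)
  expect_identical(rep$direction, "cw")
})
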