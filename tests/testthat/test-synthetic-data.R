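test_that("a noiseless sweep evaluates the intensity model row by row", {
  cal <- ref_cal()
  sw <- gen_calibration_sweep(cal, 10, noise_spec(intensity_sd = 0))
  expect_equal(nrow(sw), 19)
  ip <- intensity_pair(sw$angle_deg * pi / 180, cal)
  expect_equal(sw$i_bottom, ip$i_bottom)
  expect_equal(sw$i_upper, ip$i_upper)
  expect_identical(attr(sw, "truth"), cal)
  # an angle on the optical null returns background in both channels
  cal2 <- polar_calibration(100, 80, 45.3, 7)   # null at theta = 10 deg
  sw2 <- gen_calibration_sweep(cal2, 10, noise_spec(0))
  expect_equal(unlist(sw2[sw2$angle_deg == 10, c("i_bottom", "i_upper")]),
               c(i_bottom = 7, i_upper = 7))
})

test_that("invalid calibrations are rejected", {
  expect_error(polar_calibration(-1, 0, 45, 0))
  cal <- ref_cal(); cal$I0 <- -5
  expect_error(gen_calibration_sweep(cal, 10), "I0")
})

test_that("noiseless tracks carry the exact projected-angle series", {
  gt <- ground_truth(model = motion_model(v = 0.5, pitch_um = 0.7, phi = 0),
                     duration = 2, seed = 1)
  tk <- gen_track(gt, noise_spec(0, 0, 0))
  pa <- projected_angle(tk$truth$t, gt$model$yr)
  i <- pa$defined
  expect_equal(tk$truth$angle_deg[i], (pa$angle[i] * 180 / pi))
  expect_identical(tk$truth$angle_defined[i], rep(1L, sum(i)))
  # noisy and truth agree exactly at zero noise
  expect_equal(tk$noisy$x_um, tk$truth$x_um)
  expect_equal(tk$noisy$i_bottom, tk$truth$i_bottom)
})

test_that("the protofilament-tracking control never rotates its polarization", {
  gt <- ground_truth(model = motion_model(phi = 0.6, omega_roll = 0,
                                          omega_yaw = 0),
                     duration = 2, seed = 1)
  tk <- gen_track(gt, noise_spec(0, 0, 0))
  expect_equal(diff(range(tk$truth$angle_deg)), 0)
  expect_equal(diff(range(tk$truth$i_bottom)), 0)
})

test_that("seeds change the noise realisation but never the ground truth", {
  gt1 <- ground_truth(duration = 1, seed = 1)
  gt2 <- ground_truth(duration = 1, seed = 2)
  t1 <- gen_track(gt1, noise_spec(3, 10, 0))
  t2 <- gen_track(gt2, noise_spec(3, 10, 0))
  expect_identical(t1$truth, t2$truth)
  expect_false(identical(t1$noisy$x_um, t2$noisy$x_um))
  # same seed reproduces bit-identically
  expect_identical(t1$noisy, gen_track(gt1, noise_spec(3, 10, 0))$noisy)
})

test_that("a zero-length rod flags every angle undefined", {
  gt <- ground_truth(model = motion_model(geom = structure(
    list(diameter = 0, length = 0, r = 0), class = "rod_geometry")),
    duration = 0.2, seed = 1)
  tk <- gen_track(gt, noise_spec(0, 0, 0))
  expect_true(all(is.na(tk$truth$angle_deg)))
  expect_true(all(tk$truth$angle_defined == 0L))
})

test_that("rendered spots are round at focus and vanish at zero amplitude", {
  tr <- data.frame(frame = 0:4, t = (0:4) / 100, x_um = 0, y_um = 0, z_um = 0,
                   i_bottom = 1500, i_upper = 0, dop = 1,
                   angle_deg = NA_real_, angle_defined = 0L)
  st <- gen_image_stack(tr, noise = noise_spec(0, 0, 0), seed = 1)
  expect_equal(st$truth$s_y_px / st$truth$s_x_px, rep(1, 5))
  # upper spot (smaller row indices) absent above background
  ny <- dim(st$stack)[1]
  upper_half <- st$stack[1:floor(ny / 2 - 2), , 1]
  expect_lt(max(upper_half), 1e-6)
  expect_gt(max(st$stack[, , 1]), 10)
})

test_that("overlapping displacer spots trigger a degeneracy warning", {
  tr <- data.frame(frame = 0L, t = 0, x_um = 0, y_um = 0, z_um = 0,
                   i_bottom = 100, i_upper = 100, dop = 0,
                   angle_deg = NA_real_, angle_defined = 0L)
  expect_warning(gen_image_stack(tr, psf_sd = 110, displacer_offset = 100,
                                 noise = noise_spec(0, 0, 0)),
                 "degenerate")
})

test_that("render-and-fit recovers positions within 0.1 px at SNR 10", {
  gt <- ground_truth(model = motion_model(phi = 0.8), duration = 0.4, seed = 4)
  tk <- gen_track(gt, noise_spec(0, 0, 0))
  st <- gen_image_stack(tk$truth, noise = noise_spec(0, 0, 0), seed = 1)
  # per-pixel noise for SNR 10 on the dimmer typical spot amplitude
  amp <- median(tk$truth$i_bottom) / (2 * pi * (110 / 42)^2)
  stn <- gen_image_stack(tk$truth,
                         noise = noise_spec(intensity_sd = amp / 10,
                                            background = 5 * amp / 10),
                         seed = 7)
  out <- track_stack(stn$stack, stn$displacer_offset_px)
  i <- out$ok
  ex <- (out$x_um - out$x_um[1]) - (tk$truth$x_um - tk$truth$x_um[1])
  ey <- (out$y_um - out$y_um[1]) - (tk$truth$y_um - tk$truth$y_um[1])
  px_um <- 42 / 1000
  expect_gt(mean(i), 0.95)
  expect_lt(sqrt(mean(ex[i]^2)) / px_um, 0.1)
  expect_lt(sqrt(mean(ey[i]^2)) / px_um, 0.1)
})

test_that("image-pipeline localization error grows with intensity noise", {
  gt <- ground_truth(duration = 0.25, seed = 9)
  tk <- gen_track(gt, noise_spec(0, 0, 0))
  rmse_at <- function(sd) {
    st <- gen_image_stack(tk$truth, noise = noise_spec(intensity_sd = sd,
                                                       background = 3 * sd),
                          seed = 11)
    out <- track_stack(st$stack, st$displacer_offset_px)
    i <- out$ok
    j <- which(i)[1]                       # reference: first converged frame
    sqrt(mean(((out$x_um - out$x_um[j]) -
                 (tk$truth$x_um - tk$truth$x_um[j]))[i]^2))
  }
  errs <- vapply(c(0.02, 0.2, 0.6), rmse_at, 0)
  expect_true(all(diff(errs) > 0))
})

test_that("stacks round-trip through 16-bit TIFF", {
  arr <- array(runif(16 * 16 * 3, 0, 60000), c(16, 16, 3))
  path <- tempfile(fileext = ".tiff")
  on.exit(unlink(path))
  write_stack(arr, path)
  back <- read_stack(path)
  expect_lt(max(abs(back - arr)), 1.01)   # one grey level (quantisation)
  expect_error(write_stack(arr * 2, path), "65535")
})
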