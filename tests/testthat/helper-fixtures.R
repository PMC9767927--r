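# shared fixtures: the reference calibration of the polarization optics and
# a default coupled-rotation motion model
ref_cal <- function(b = 19.5) polar_calibration(127.5, 99.3, 45.3, b)

ref_track <- function(phi = 0, yaw_sign = -1, duration = 6, seed = 1,
                      noise = noise_spec(0, 0, 0), ...) {
  gt <- ground_truth(model = motion_model(phi = phi, yaw_sign = yaw_sign, ...),
                     duration = duration, seed = seed)
  gen_track(gt, noise)
}

# attach estimated angles to a noisy track
with_angles <- function(track, cal = ref_cal()) {
  est <- estimate_angle_series(track$i_bottom, track$i_upper, cal)
  track$angle_deg <- est$angle_deg
  track$angle_defined <- as.integer(est$defined)
  track
}
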