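# Generators for every input the analysis pipeline consumes: calibration
# sweeps, ground-truthed tracks, and dark-field image stacks. Defaults follow
# the study conditions: a particle advancing at ~0.5 um/s along X while
# orbiting the microtubule with ~0.7 um pitch, yawing 180 degrees per orbit,
# imaged at 100 frames/s on 42-nm pixels through the two-channel polarization
# model.

#' Noise specification for the generators
#'
#' @param intensity_sd additive Gaussian SD per channel (counts).
#' @param localization_sd isotropic per-axis localization noise (nm).
#' @param background additional constant background (counts); for image
#'   stacks this is a per-pixel offset, for tracks it is added to both
#'   channels.
#' @return an object of class \code{noise_spec}. All fields must be >= 0.
#' @export
noise_spec <- function(intensity_sd = 3, localization_sd = 10, background = 0) {
  stopifnot(intensity_sd >= 0, localization_sd >= 0, background >= 0)
  structure(list(intensity_sd = intensity_sd,
                 localization_sd = localization_sd,
                 background = background), class = "noise_spec")
}

#' Motion model of a rolling, yawing rod on a helical track
#'
#' Bundles the helix, yaw/roll and rod-geometry parameters. By default the
#' coupled-rotation relations hold: \code{omega_roll = omega_helix} and
#' \code{omega_yaw = yaw_sign * omega_helix / 2} (180 degrees of yaw per
#' orbit); pass \code{omega_roll}/\code{omega_yaw} explicitly to override
#' (e.g. \code{omega_yaw = 0} for a protofilament-tracking control that never
#' rotates its polarization unidirectionally).
#'
#' @param v translational velocity (um/s), default 0.5.
#' @param pitch_um helix pitch (um), default 0.7; sets
#'   \code{omega_helix = 2 pi v / pitch_um} when \code{omega_helix} is not
#'   given.
#' @param omega_helix orbital angular velocity (rad/s); positive =
#'   left-handed.
#' @param h_nm orbit radius (nm), default 35 (microtubule radius plus rod
#'   radius).
#' @param phi initial phase angle (rad).
#' @param yaw_sign +1 counterclockwise, -1 clockwise yaw (default -1).
#' @param omega_roll,omega_yaw explicit overrides (rad/s).
#' @param geom a [rod_geometry].
#' @return an object of class \code{motion_model} containing
#'   [helix_params()], [yaw_roll_params()] and the geometry.
#' @export
motion_model <- function(v = 0.5, pitch_um = 0.7, omega_helix = NULL,
                         h_nm = 35, phi = 0, yaw_sign = -1,
                         omega_roll = NULL, omega_yaw = NULL,
                         geom = rod_geometry()) {
  if (is.null(omega_helix)) omega_helix <- 2 * pi * v / pitch_um
  if (is.null(omega_roll)) omega_roll <- omega_helix
  if (is.null(omega_yaw)) omega_yaw <- yaw_sign * abs(omega_helix) / 2
  structure(list(hp = helix_params(v = v, omega_helix = omega_helix, h = h_nm),
                 yr = yaw_roll_params(omega_roll = omega_roll,
                                      omega_yaw = omega_yaw, phi = phi),
                 geom = geom),
            class = "motion_model")
}

#' Ground-truth specification for track generation
#'
#' @param model a [motion_model].
#' @param calibration a [polar_calibration]; defaults to the reference
#'   calibration (I0 = 127.5, zeta = 99.3 deg, eta = 45.3 deg, b = 19.5).
#' @param frame_rate frames per second (default 100), > 0.
#' @param duration recording length (s), > 0 (default 6).
#' @param seed integer RNG seed.
#' @return an object of class \code{ground_truth_spec}.
#' @export
ground_truth <- function(model = motion_model(),
                         calibration = polar_calibration(127.5, 99.3, 45.3, 19.5),
                         frame_rate = 100, duration = 6, seed = 1L) {
  stopifnot(frame_rate > 0, duration > 0)
  structure(list(model = model, calibration = calibration,
                 frame_rate = frame_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "ground_truth_spec")
}

#' Generate a polarizer calibration sweep
#'
#' Emulates the angular calibration: a linear polarizer rotated from 0 to 180
#' degrees in fixed intervals while both channel intensities are recorded.
#'
#' @param cal a [polar_calibration] (the ground truth).
#' @param angle_step polarizer step (degrees), in (0, 90].
#' @param noise a [noise_spec]; only \code{intensity_sd} and
#'   \code{background} apply.
#' @param seed RNG seed.
#' @return a data.frame (\code{angle_deg}, \code{i_bottom}, \code{i_upper})
#'   with the ground-truth calibration attached as attribute \code{truth}.
#' @export
gen_calibration_sweep <- function(cal, angle_step = 10,
                                  noise = noise_spec(intensity_sd = 0),
                                  seed = 1L) {
  stopifnot(inherits(cal, "polar_calibration"), angle_step > 0,
            angle_step <= 90)
  if (cal$I0 <= 0) stop("non-positive I0")
  set.seed(seed)
  ang <- seq(0, 180, by = angle_step)
  ip <- intensity_pair(ang * pi / 180, cal)
  out <- data.frame(angle_deg = ang,
                    i_bottom = ip$i_bottom + noise$background +
                      stats::rnorm(length(ang), 0, noise$intensity_sd),
                    i_upper = ip$i_upper + noise$background +
                      stats::rnorm(length(ang), 0, noise$intensity_sd))
  attr(out, "truth") <- cal
  out
}

#' Generate a ground-truthed noisy track
#'
#' Samples the motion model at the frame rate: positions are the centre
#' trajectory plus isotropic localization noise; channel intensities are the
#' two-channel model evaluated at the exact projected angle, plus intensity
#' noise. The exact per-frame angle travels with the truth track; a
#' zero-length rod flags every angle undefined.
#'
#' @param gt a [ground_truth_spec].
#' @param noise a [noise_spec].
#' @return a list with elements \code{truth} and \code{noisy}, both track
#'   data.frames in the standard schema (see [write_track()]); \code{truth}
#'   carries exact positions/angles, \code{noisy} carries the observed
#'   columns with \code{angle_deg = NA} (estimation is the analyser's job).
#' @export
gen_track <- function(gt, noise = noise_spec()) {
  stopifnot(inherits(gt, "ground_truth_spec"), inherits(noise, "noise_spec"))
  set.seed(gt$seed)
  n <- floor(gt$duration * gt$frame_rate) + 1
  t <- (seq_len(n) - 1) / gt$frame_rate
  m <- gt$model
  ctr <- helix_center(t, m$hp)           # x in um (v in um/s), y/z in nm (h in nm)
  x_um <- ctr[, 1]
  y_um <- ctr[, 2] / 1000
  z_um <- ctr[, 3] / 1000
  if (m$geom$r > 0) {
    pa <- projected_angle(t, m$yr)
    ang <- pa$angle
    def <- pa$defined
  } else {
    ang <- rep(NA_real_, n)
    def <- rep(FALSE, n)
  }
  ip <- intensity_pair(ifelse(def, ang, 0), gt$calibration)
  # angle-undefined frames still scatter: the vertical rod projects the
  # polarization null, i.e. both channels at background
  ip$i_bottom[!def] <- gt$calibration$b
  ip$i_upper[!def] <- gt$calibration$b
  truth <- data.frame(frame = seq_len(n) - 1L, t = t,
                      x_um = x_um, y_um = y_um, z_um = z_um,
                      i_bottom = ip$i_bottom, i_upper = ip$i_upper,
                      dop = dop(ip),
                      angle_deg = ifelse(def, ang * 180 / pi, NA_real_),
                      angle_defined = as.integer(def))
  loc <- noise$localization_sd / 1000    # nm -> um
  noisy <- truth
  noisy$x_um <- x_um + stats::rnorm(n, 0, loc)
  noisy$y_um <- y_um + stats::rnorm(n, 0, loc)
  noisy$z_um <- z_um + stats::rnorm(n, 0, loc)
  noisy$i_bottom <- ip$i_bottom + noise$background +
    stats::rnorm(n, 0, noise$intensity_sd)
  noisy$i_upper <- ip$i_upper + noise$background +
    stats::rnorm(n, 0, noise$intensity_sd)
  noisy$dop <- dop(noisy$i_bottom, noisy$i_upper)
  noisy$angle_deg <- NA_real_
  noisy$angle_defined <- 0L
  list(truth = truth, noisy = noisy)
}

#' Render a track as a dark-field image stack
#'
#' Each frame holds two axis-aligned Gaussian spots, displaced symmetrically
#' along camera Y by the beam displacer, whose integrated intensities are the
#' two channel intensities and whose width ratio \code{s_y/s_x} encodes Z
#' through the astigmatism slope. Widths are applied at constant
#' \code{s_x * s_y} so defocus reshapes rather than brightens the spot; at
#' \code{Z = 0} both widths equal \code{psf_sd}.
#'
#' @param track a track data.frame (truth or noisy) with \code{x_um, y_um,
#'   z_um, i_bottom, i_upper}.
#' @param psf_sd in-focus Gaussian SD (nm), default 110.
#' @param displacer_offset spot separation along Y (nm), default 1260.
#' @param astig_slope astigmatism calibration (um per unit width ratio),
#'   default 0.98.
#' @param noise a [noise_spec]; \code{intensity_sd} is per-pixel read noise
#'   and \code{background} a constant offset.
#' @param pixel_size_nm pixel size (nm), default 42.
#' @param pad_px margin around the trajectory (px), default 12.
#' @param seed RNG seed.
#' @return a list with \code{stack} (array \code{[row, col, frame]}, counts),
#'   \code{truth} (data.frame of per-frame spot centres in px and rendered
#'   widths) and the geometry (\code{pixel_size_nm, displacer_offset_px}).
#'   Spots closer than \code{2 psf_sd} trigger a warning (fit degeneracy).
#' @export
gen_image_stack <- function(track, psf_sd = 110, displacer_offset = 1260,
                            astig_slope = 0.98, noise = noise_spec(),
                            pixel_size_nm = 42, pad_px = 12, seed = 1L) {
  stopifnot(all(c("x_um", "y_um", "z_um", "i_bottom", "i_upper") %in%
                  names(track)))
  if (displacer_offset < 2 * psf_sd)
    warning("displacer offset within 2 psf_sd: spot fits may be degenerate")
  set.seed(seed)
  px <- pixel_size_nm
  sx_px <- psf_sd / px
  off_px <- displacer_offset / px
  x_px0 <- track$x_um * 1000 / px
  y_px0 <- track$y_um * 1000 / px
  nf <- nrow(track)
  xr <- range(x_px0); yr <- range(y_px0)
  nx <- ceiling(diff(xr)) + 2 * pad_px + 1
  ny <- ceiling(diff(yr) + off_px + 6 * sx_px) + 2 * pad_px + 1
  x_px <- x_px0 - xr[1] + pad_px + 1
  y_px <- y_px0 - yr[1] + pad_px + 1 + (off_px + 6 * sx_px) / 2
  ratio <- 1 + track$z_um / astig_slope
  if (any(ratio <= 0)) stop("Z out of the astigmatic calibration range")
  sx <- sx_px / sqrt(ratio)
  sy <- sx_px * sqrt(ratio)
  stack <- array(0, dim = c(ny, nx, nf))
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  rows <- matrix(seq_len(ny), ny, nx)
  for (f in seq_len(nf)) {
    gx <- exp(-(cols - x_px[f])^2 / (2 * sx[f]^2))
    up <- track$i_upper[f] / (2 * pi * sx[f] * sy[f]) *
      gx * exp(-(rows - (y_px[f] - off_px / 2))^2 / (2 * sy[f]^2))
    bo <- track$i_bottom[f] / (2 * pi * sx[f] * sy[f]) *
      gx * exp(-(rows - (y_px[f] + off_px / 2))^2 / (2 * sy[f]^2))
    frame <- up + bo + noise$background
    if (noise$intensity_sd > 0)
      frame <- frame + stats::rnorm(length(frame), 0, noise$intensity_sd)
    stack[, , f] <- frame
  }
  truth <- data.frame(frame = seq_len(nf) - 1L,
                      x_px = x_px, y_px = y_px,
                      s_x_px = sx, s_y_px = sy,
                      i_bottom = track$i_bottom, i_upper = track$i_upper,
                      z_um = track$z_um)
  list(stack = stack, truth = truth,
       pixel_size_nm = px, displacer_offset_px = off_px)
}

#' Write / read an image stack as multi-page 16-bit grayscale TIFF
#'
#' Counts are stored divided by 2^16 - 1 (the TIFF grayscale full scale), so
#' stacks must stay within \code{[0, 65535]} counts. The ground truth should
#' travel in a JSON sidecar (see [write_manifest()]).
#'
#' @param stack numeric array \code{[row, col, frame]}.
#' @param path output file.
#' @return \code{read_stack} returns the array in counts.
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  mx <- 65535
  if (max(stack) > mx || min(stack) < 0)
    stop("stack counts outside [0, 65535]")
  pages <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  simplify2array(pages) * 65535
}
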