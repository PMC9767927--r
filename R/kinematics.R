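#' gnrtrack: rotation analysis of motor-driven gold nanorods
#'
#' Forward kinematics, polarimetry, spot tracking, trajectory quantification,
#' ratchet flux theory and a multi-motor cargo simulator for nanorod cargoes
#' rolling and yawing around microtubules. See the package vignette for the
#' underlying model and conventions.
#'
#' @section Coordinate conventions:
#' X runs along the microtubule axis toward the plus end, Z is vertical
#' (toward the objective), and Y completes a right-handed frame. Angles are
#' radians internally and degrees at every user-facing interface. In-plane
#' rod orientations live on \code{[0, 180)} degrees because the rod's
#' polarized scattering is head--tail symmetric. A positive orbital angular
#' velocity denotes the left-handed orbit (the cargo at the top of the
#' microtubule moves toward +Y while advancing toward +X).
#'
#' @keywords internal
#' @importFrom stats approx coef cor dbinom fft integrate lm median nls
#'   optimize pnorm quantile rbinom rnorm runif sd setNames t.test var
#' @importFrom utils head read.csv tail write.csv
"_PACKAGE"

# ---- parameter containers ---------------------------------------------------

#' Helical-track parameters
#'
#' Parameters of the helical path followed by the rod's geometric centre:
#' constant advance along X at velocity \code{v} while the centre orbits the
#' microtubule axis on a circle of radius \code{h} in the Y--Z plane.
#'
#' @param v translational velocity along X (micrometre/s).
#' @param omega_helix signed orbital angular velocity in the Y--Z plane
#'   (rad/s); positive is the left-handed orbit.
#' @param h orbit radius (nm), must be >= 0. The radius cancels from the
#'   projected-angle model but is needed to render 3D positions.
#' @return an object of class \code{helix_params}.
#' @export
helix_params <- function(v, omega_helix, h) {
  stopifnot(is.numeric(v), is.numeric(omega_helix), is.numeric(h), h >= 0)
  structure(list(v = v, omega_helix = omega_helix, h = h),
            class = "helix_params")
}

#' Yaw/roll rotation parameters
#'
#' Angular velocities of the rod's rotation about the vertical short axis
#' (yaw, about Z) and about the microtubule axis (roll, about X), plus the
#' initial phase angle of the rod in the image plane. In the coupled-rotation
#' model the roll is synchronised with the orbit (\code{omega_roll =
#' omega_helix}) and the yaw runs at half the orbital rate, so the rod turns
#' 180 degrees per orbit.
#'
#' @param omega_roll roll angular velocity (rad/s).
#' @param omega_yaw signed yaw angular velocity (rad/s). Under the image
#'   convention used throughout (X right, Y up, viewed from +Z) a negative
#'   value is clockwise yawing.
#' @param phi initial phase angle (rad), folded into \code{[0, pi)}.
#' @return an object of class \code{yaw_roll_params}.
#' @export
yaw_roll_params <- function(omega_roll, omega_yaw, phi = 0) {
  stopifnot(is.numeric(omega_roll), is.numeric(omega_yaw), is.numeric(phi))
  structure(list(omega_roll = omega_roll, omega_yaw = omega_yaw,
                 phi = phi %% pi),
            class = "yaw_roll_params")
}

#' Rod geometry
#'
#' @param diameter rod diameter (nm), default 40.
#' @param length rod length (nm), default 68; must be >= diameter.
#' @return an object of class \code{rod_geometry} with half-length \code{r}.
#' @export
rod_geometry <- function(diameter = 40, length = 68) {
  stopifnot(diameter > 0, length >= diameter)
  structure(list(diameter = diameter, length = length, r = length / 2),
            class = "rod_geometry")
}

# ---- elemental rotations ----------------------------------------------------

#' Elemental rotation matrices
#'
#' Right-handed active rotations about the X, Y and Z axes.
#'
#' @param angle rotation angle in radians.
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @export
rot_x <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(1, 0, 0,
           0, c, s,
           0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, 0, -s,
           0, 1, 0,
           s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, s, 0,
           -s, c, 0,
           0, 0, 1), 3, 3)
}

# ---- helical track ----------------------------------------------------------

#' Centre position on the helical track
#'
#' The rod centre advances along X at constant velocity while orbiting the
#' microtubule axis on a circle of radius \code{h}, starting at the top of the
#' orbit: \code{(v t, h cos(pi/2 - w t), h sin(pi/2 - w t))}.
#'
#' @param t time (s), may be a vector.
#' @param hp a [helix_params] object.
#' @return an \code{n x 3} matrix of positions; X in micrometres if \code{v}
#'   is in micrometres/s and Y, Z in the units of \code{h}.
#' @export
helix_center <- function(t, hp) {
  stopifnot(inherits(hp, "helix_params"))
  ph <- pi / 2 - hp$omega_helix * t
  cbind(x = hp$v * t, y = hp$h * cos(ph), z = hp$h * sin(ph))
}

#' Full rod pose on the helical track
#'
#' Composes the yaw and roll rotations with the helical displacement of the
#' centre. The rod starts parallel to the sample plane at phase angle
#' \code{phi}; the pose is the extrinsic rotation sequence (yaw about Z, then
#' a null pitch about Y, then roll about X) applied to the tip/end offsets,
#' plus the helical centre displacement. Closed forms:
#' \deqn{tip = (r\cos\psi + vt,\; r\cos(\omega_R t)\sin\psi + Y_c,\;
#'       r\sin(\omega_R t)\sin\psi + Z_c)}
#' with \eqn{\psi = \omega_Y t + \phi}, and \code{end} mirrored through the
#' centre.
#'
#' @param t time (s), may be a vector.
#' @param hp a [helix_params] object. Positions mix the units of \code{v*t}
#'   and \code{h}/\code{r}; pass consistent units (nm throughout is typical).
#' @param yr a [yaw_roll_params] object.
#' @param geom a [rod_geometry] object.
#' @return a list with \code{n x 3} matrices \code{tip}, \code{center},
#'   \code{end}; always \code{tip + end = 2 center}.
#' @export
rod_pose <- function(t, hp, yr, geom) {
  stopifnot(inherits(yr, "yaw_roll_params"), inherits(geom, "rod_geometry"))
  ctr <- helix_center(t, hp)
  psi <- yr$omega_yaw * t + yr$phi
  roll <- yr$omega_roll * t
  off <- cbind(geom$r * cos(psi),
               geom$r * cos(roll) * sin(psi),
               geom$r * sin(roll) * sin(psi))
  list(tip = ctr + off, center = ctr, end = ctr - off)
}

#' Pose by explicit matrix products
#'
#' Evaluates the pose by multiplying the elemental rotation matrices against
#' the initial tip/centre/end columns, without using the closed forms of
#' [rod_pose]. Used as an algebraic cross-check of the closed forms.
#'
#' @inheritParams rod_pose
#' @return same structure as [rod_pose].
#' @export
rod_pose_matrix <- function(t, hp, yr, geom) {
  ctr <- helix_center(t, hp)
  n <- length(t)
  tip <- end <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  p0 <- cbind(tip = c(geom$r * cos(yr$phi), geom$r * sin(yr$phi), 0),
              center = c(0, 0, 0),
              end = c(geom$r * cos(yr$phi + pi), geom$r * sin(yr$phi + pi), 0))
  for (i in seq_len(n)) {
    rot <- rot_x(yr$omega_roll * t[i]) %*% rot_y(0) %*% rot_z(yr$omega_yaw * t[i])
    p <- rot %*% p0
    tip[i, ] <- p[, "tip"] + ctr[i, ]
    end[i, ] <- p[, "end"] + ctr[i, ]
  }
  list(tip = tip, center = ctr, end = end)
}

# ---- projected angle --------------------------------------------------------

#' In-plane projected rod angle
#'
#' Orientation of the rod projected onto the image (X--Y) plane, the quantity
#' reported by the polarization measurement. Computed from the two-argument
#' arctangent of the tip-to-end vector, which avoids the tangent singularities
#' of the equivalent form \code{arctan(cos(w_R t) tan(w_Y t + phi))}, and
#' folded to \code{[0, pi)}.
#'
#' The angle is undefined where the projection collapses to a point (the rod
#' momentarily vertical: \code{cos(psi) = 0} and \code{cos(w_R t) = 0}
#' simultaneously); such samples are flagged.
#'
#' @param t time (s), may be a vector.
#' @param yr a [yaw_roll_params] object.
#' @param tol collapse tolerance on the projected tip-to-end length, as a
#'   fraction of the rod length (default 1e-9).
#' @return a data.frame with columns \code{t}, \code{angle} (rad, in
#'   \code{[0, pi)}) and \code{defined} (logical).
#' @export
projected_angle <- function(t, yr, tol = 1e-9) {
  stopifnot(inherits(yr, "yaw_roll_params"))
  psi <- yr$omega_yaw * t + yr$phi
  dx <- cos(psi)
  dy <- cos(yr$omega_roll * t) * sin(psi)
  defined <- sqrt(dx^2 + dy^2) > tol
  ang <- atan2(dy, dx) %% pi
  ang[!defined] <- NA_real_
  data.frame(t = t, angle = ang, defined = defined)
}

#' Unwrap a 180-degree-periodic angle series
#'
#' Adjusts successive samples of an orientation series (period 180 degrees)
#' by multiples of the half-turn so that frame-to-frame jumps are minimised,
#' yielding a continuous trace suitable for net-rotation bookkeeping.
#'
#' @param angle angle series in radians (values interpreted modulo pi);
#'   NA samples are carried through and bridged by the nearest earlier value.
#' @param period period of the series (default \code{pi}; use 180 for
#'   degree-valued series).
#' @return the unwrapped series (same length, same units).
#' @export
unwrap_angle <- function(angle, period = pi) {
  n <- length(angle)
  if (n == 0) return(angle)
  out <- numeric(n)
  out[1] <- angle[1]
  last <- angle[1]
  for (i in seq_len(n)[-1]) {
    a <- angle[i]
    if (is.na(a)) { out[i] <- NA_real_; next }
    if (is.na(last)) { out[i] <- a; last <- a; next }
    d <- (a - last) %% period
    if (d > period / 2) d <- d - period
    out[i] <- last + d
    last <- out[i]
  }
  out
}

#' Classify the polarization-rotation pattern
#'
#' Simulates one orbital period of the coupled model (roll synchronised to
#' the orbit, yaw at half the orbital rate) for a given initial phase angle
#' and yaw direction, and classifies the projected-angle series as
#' counterclockwise, clockwise, or oscillatory. The series is unidirectional
#' when its net unwrapped rotation per orbital period is within
#' \code{unidir_tol} of a half turn (180 degrees); the sign of the net
#' rotation then gives the apparent rotation sense of the polarization.
#'
#' @param phi initial phase angle (radians, in \code{[0, pi)}).
#' @param yaw_sign +1 for counterclockwise yawing, -1 for clockwise yawing
#'   (default -1, the clockwise-yaw illustration case).
#' @param unidir_tol fractional tolerance on |net rotation| = 180 degrees for
#'   calling a series unidirectional (default 0.1).
#' @param n_samples samples per orbital period (default 2000).
#' @return one of \code{"counterclockwise"}, \code{"clockwise"},
#'   \code{"oscillatory"}.
#' @export
classify_pattern <- function(phi, yaw_sign = -1, unidir_tol = 0.1,
                             n_samples = 2000) {
  stopifnot(phi >= 0, phi < pi, yaw_sign %in% c(-1, 1))
  w <- 2 * pi                       # one orbit per unit time
  yr <- yaw_roll_params(omega_roll = w, omega_yaw = yaw_sign * w / 2,
                        phi = phi)
  t <- seq(0, 1, length.out = n_samples + 1)
  pa <- projected_angle(t, yr)
  unwrapped <- unwrap_angle(pa$angle)
  net <- unwrapped[length(unwrapped)] - unwrapped[1]
  if (abs(abs(net) - pi) <= unidir_tol * pi) {
    if (net > 0) "counterclockwise" else "clockwise"
  } else {
    "oscillatory"
  }
}
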