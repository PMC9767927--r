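# Order-of-magnitude torsional mechanics of the motor linker and coating
# arithmetic for the rod cargo. Pure closed forms; units are stated per
# argument (torque in pN nm, lengths in nm, modulus in GPa with
# 1 GPa = 1000 pN/nm^2).

GPA_TO_PN_PER_NM2 <- 1000

#' Torsion parameters of the motor linker
#'
#' The motor--streptavidin linker is approximated as an elastic cylinder
#' twisted by the torque of one step.
#'
#' @param t_step torque per step (pN nm), default 170.
#' @param length cylinder length L (nm), default 12.
#' @param diameter cylinder diameter d (nm), default 5.
#' @param g_modulus modulus of rigidity G (GPa), default 1.
#' @return an object of class \code{torsion_params}.
#' @export
torsion_params <- function(t_step = 170, length = 12, diameter = 5,
                           g_modulus = 1) {
  stopifnot(t_step > 0, length > 0, diameter > 0, g_modulus > 0)
  structure(list(t_step = t_step, length = length, diameter = diameter,
                 g_modulus = g_modulus), class = "torsion_params")
}

#' Polar moment of inertia of a cylinder section
#'
#' \code{K = pi d^4 / 32}.
#'
#' @param diameter cylinder diameter (nm), > 0.
#' @return K (nm^4).
#' @export
polar_moment <- function(diameter) {
  stopifnot(all(diameter > 0))
  pi * diameter^4 / 32
}

#' Twist angle per step of the elastic linker
#'
#' \code{theta_step = T_step L / (K G)} with \code{K = pi d^4/32} and G
#' converted from GPa to pN/nm^2 (factor exactly 1000).
#'
#' @param p a [torsion_params].
#' @return a list with \code{radians}, \code{degrees} and \code{degrees_rounded}
#'   (nearest degree).
#' @export
twist_angle <- function(p = torsion_params()) {
  stopifnot(inherits(p, "torsion_params"))
  K <- polar_moment(p$diameter)
  th <- p$t_step * p$length / (K * p$g_modulus * GPA_TO_PN_PER_NM2)
  list(radians = th, degrees = th * 180 / pi,
       degrees_rounded = round(th * 180 / pi))
}

#' Yaw angle per motor step
#'
#' A rod that yaws 180 degrees per helix pitch turns
#' \code{180 * step / pitch} degrees per forward step.
#'
#' @param pitch_nm helix pitch (nm), > 0 (default 700).
#' @param step_nm step length (nm), default 8 (the tubulin dimer repeat).
#' @return degrees per step.
#' @export
yaw_per_step <- function(pitch_nm = 700, step_nm = 8) {
  stopifnot(all(pitch_nm > 0), all(step_nm > 0))
  180 * step_nm / pitch_nm
}

#' Lateral excursion of a motor under cargo rotation
#'
#' A motor bound at moment arm \code{arm_nm} from the yaw axis moves
#' laterally by \code{arm * tan(angle)} when the cargo turns by
#' \code{angle_deg}.
#'
#' @param arm_nm moment arm (nm), > 0; the rod radius (20 nm) and half-length
#'   (34 nm) bracket the physical range.
#' @param angle_deg rotation (degrees).
#' @return lateral displacement (nm).
#' @export
lateral_excursion <- function(arm_nm, angle_deg) {
  stopifnot(all(arm_nm > 0))
  arm_nm * tan(angle_deg * pi / 180)
}

#' Normalise a lateral displacement to binding-site units
#'
#' @param displacement_nm lateral displacement (nm).
#' @param site_spacing_nm off-axis binding-site spacing (nm), default 5.1
#'   (adjacent protofilaments).
#' @return displacement in lattice units.
#' @export
normalized_offset <- function(displacement_nm, site_spacing_nm = 5.1) {
  stopifnot(all(site_spacing_nm > 0))
  displacement_nm / site_spacing_nm
}

#' Coating parameters of the motor-covered rod
#'
#' @param rod a [rod_geometry].
#' @param footprint_nm2 surface area occupied per motor (nm^2), default 100.
#' @param accessible_fraction fraction of attached motors positioned to
#'   engage the microtubule, default 0.25.
#' @param duty_ratio fraction of the mechanochemical cycle spent
#'   force-generating, default 0.2.
#' @return an object of class \code{coating_params}.
#' @export
coating_params <- function(rod = rod_geometry(), footprint_nm2 = 100,
                           accessible_fraction = 0.25, duty_ratio = 0.2) {
  stopifnot(footprint_nm2 > 0,
            accessible_fraction > 0, accessible_fraction <= 1,
            duty_ratio > 0, duty_ratio <= 1)
  structure(list(rod = rod, footprint_nm2 = footprint_nm2,
                 accessible_fraction = accessible_fraction,
                 duty_ratio = duty_ratio), class = "coating_params")
}

#' Motor capacity of the rod surface
#'
#' Closed-cylinder surface area (lateral \code{pi d L} plus two end disks)
#' divided by the per-motor footprint.
#'
#' @param cp a [coating_params].
#' @return a list with \code{area_nm2}, \code{capacity} (raw) and
#'   \code{capacity_rounded} (one significant figure).
#' @export
surface_capacity <- function(cp = coating_params()) {
  stopifnot(inherits(cp, "coating_params"))
  d <- cp$rod$diameter; L <- cp$rod$length
  area <- pi * d * L + 2 * pi * (d / 2)^2
  cap <- area / cp$footprint_nm2
  list(area_nm2 = area, capacity = cap, capacity_rounded = signif(cap, 1))
}

#' Expected number of simultaneously engaged motors
#'
#' \code{capacity * accessible_fraction * duty_ratio}.
#'
#' @param cp a [coating_params].
#' @param capacity motor capacity (default: the one-significant-figure
#'   surface capacity of \code{cp}).
#' @return expected engaged-motor count.
#' @export
engaged_motors <- function(cp = coating_params(),
                           capacity = surface_capacity(cp)$capacity_rounded) {
  capacity * cp$accessible_fraction * cp$duty_ratio
}
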