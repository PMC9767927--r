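# Closed-form flux of the two-state noise-driven ratchet with laterally
# offset start positions. Lengths are in lattice units (off-axis binding-site
# spacing = 1); the barrier of the asymmetric potential sits at alpha ahead of
# a particle's home well and 1 - alpha behind it. While the potential is off
# the particle diffuses freely (diffusion constant 1 in lattice units); the
# flux is evaluated after 1/gamma units of time, when the potential switches
# back on and captures particles past the barriers.

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Parameters of the offset two-state ratchet
#'
#' @param alpha barrier asymmetry factor, in (0, 1).
#' @param gamma drag coefficient (1/s); the free-diffusion interval is
#'   1/gamma.
#' @param d lateral start offset of the displaced particles, in [0, 1)
#'   lattice units.
#' @return an object of class \code{ratchet_params}.
#' @export
ratchet_params <- function(alpha, gamma, d = 0) {
  stopifnot(alpha > 0, alpha < 1, gamma > 0, d >= 0, d < 1)
  structure(list(alpha = alpha, gamma = gamma, d = d),
            class = "ratchet_params")
}

#' Free-diffusion probability density of the ratchet's off state
#'
#' Gaussian density of a particle released at offset \code{d}:
#' \code{P(x; t) = exp(-(x - d)^2 / (4 t)) / (2 sqrt(pi t))} (mean \code{d},
#' variance \code{2 t}).
#'
#' @param x position (lattice units), may be a vector.
#' @param t elapsed time, > 0.
#' @param d start offset.
#' @return density values.
#' @export
ratchet_density <- function(x, t, d = 0) {
  if (t <= 0) stop("t must be > 0")
  exp(-(x - d)^2 / (4 * t)) / (2 * sqrt(pi * t))
}

#' Flux of the centred particle
#'
#' Closed form
#' \code{J0 = (gamma/4) (erfc(alpha sqrt(gamma) / 2) -
#' erfc((1 - alpha) sqrt(gamma) / 2))}: the imbalance between forward and
#' backward barrier crossings after 1/gamma units of free diffusion, at the
#' gamma/4 normalisation in which the fluxes are reported.
#'
#' @param alpha asymmetry factor in (0, 1).
#' @param gamma drag coefficient, > 0.
#' @return the flux J0 (negative when alpha > 1/2: the nearer barrier behind
#'   the off-axis direction wins).
#' @export
flux_j0 <- function(alpha, gamma) {
  stopifnot(all(alpha > 0 & alpha < 1), all(gamma > 0))
  (gamma / 4) * (erfc(alpha / 2 * sqrt(gamma)) -
                   erfc((1 - alpha) / 2 * sqrt(gamma)))
}

#' Flux of a laterally displaced particle
#'
#' Closed form for a particle starting at \code{+d} (sign \code{"+"}) or
#' \code{-d} (sign \code{"-"}):
#' \code{J(+/-d) = (gamma/4) (erfc((alpha -/+ d) sqrt(gamma) / 2) -
#' erfc((1 - alpha +/- d) sqrt(gamma) / 2))}. At \code{d = 0} both branches
#' reduce to [flux_j0()].
#'
#' @inheritParams flux_j0
#' @param d lateral start offset in [0, 1).
#' @param sign \code{"+"} or \code{"-"}.
#' @return the flux.
#' @export
flux_jd <- function(alpha, gamma, d, sign = c("+", "-")) {
  sign <- match.arg(sign)
  stopifnot(all(alpha > 0 & alpha < 1), all(gamma > 0), all(d >= 0 & d < 1))
  s <- if (sign == "+") 1 else -1
  (gamma / 4) * (erfc((alpha - s * d) / 2 * sqrt(gamma)) -
                   erfc((1 - alpha + s * d) / 2 * sqrt(gamma)))
}

#' Net flux of the three-particle ensemble
#'
#' \code{J(-d) + J0 + J(+d)}: the summed flux of one centred and two
#' oppositely displaced particles, modelling the posterior/anterior motors
#' shifted by the cargo's rotation.
#'
#' @inheritParams flux_jd
#' @return the net flux.
#' @export
net_flux <- function(alpha, gamma, d) {
  flux_jd(alpha, gamma, d, "-") + flux_j0(alpha, gamma) +
    flux_jd(alpha, gamma, d, "+")
}

#' Diffusion standard deviation per switching interval
#'
#' SD of the free diffusion accumulated over one off interval
#' (\code{t = 1/gamma}, diffusion constant 1): \code{sqrt(2/gamma)}.
#'
#' @param gamma drag coefficient, > 0.
#' @return SD in lattice units.
#' @export
diffusion_sd <- function(gamma) {
  stopifnot(all(gamma > 0))
  sqrt(2 / gamma)
}

#' Scan the net flux over the lateral offset
#'
#' Evaluates the three fluxes and their sum on a d-grid, and reports the
#' offset minimising the net flux.
#'
#' @param alpha asymmetry factor.
#' @param gamma drag coefficient.
#' @param d_max scan limit (default just under 1).
#' @param step grid step (default 0.005, fine enough to resolve the minimum
#'   location unambiguously).
#' @return a data.frame (\code{d, j_minus, j0, j_plus, net}) with the argmin
#'   in attribute \code{d_min}.
#' @export
ratchet_scan <- function(alpha, gamma, d_max = 0.995, step = 0.005) {
  stopifnot(d_max < 1, step > 0)
  d <- seq(0, d_max, by = step)
  out <- data.frame(
    d = d,
    j_minus = flux_jd(alpha, gamma, d, "-"),
    j0 = flux_j0(alpha, gamma),
    j_plus = flux_jd(alpha, gamma, d, "+"))
  out$net <- out$j_minus + out$j0 + out$j_plus
  attr(out, "d_min") <- d[which.min(out$net)]
  out
}
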