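# Two-channel polarization model: a polarizing beam displacer splits the
# scattered light into "bottom" and "upper" spots whose intensities encode the
# in-plane rod orientation theta:
#   I_bottom = I0 cos^2(theta + zeta) cos^2(theta + zeta - eta)        + b
#   I_upper  = I0 cos^2(theta + zeta) cos^2(theta + zeta - eta + pi/2) + b
# zeta is the incident-beam polarization phase, eta the displacer phase, b the
# background. The sum I_bottom + I_upper - 2b = I0 cos^2(theta + zeta).

#' Polarization calibration parameters
#'
#' @param I0 amplitude (counts), > 0.
#' @param zeta_deg incident-beam polarization phase (degrees).
#' @param eta_deg beam-displacer phase (degrees).
#' @param b background intensity per channel (counts), >= 0.
#' @param se optional named vector of per-parameter standard errors
#'   (\code{I0}, \code{zeta_deg}, \code{eta_deg}, \code{b}), attached by
#'   [fit_calibration()].
#' @return an object of class \code{polar_calibration}. Phases are stored in
#'   radians (\code{zeta}, \code{eta}) alongside the degree values.
#' @export
polar_calibration <- function(I0, zeta_deg, eta_deg, b, se = NULL) {
  stopifnot(I0 > 0, b >= 0)
  structure(list(I0 = I0,
                 zeta = zeta_deg * pi / 180, eta = eta_deg * pi / 180,
                 zeta_deg = zeta_deg, eta_deg = eta_deg,
                 b = b, se = se),
            class = "polar_calibration")
}

#' @export
print.polar_calibration <- function(x, ...) {
  cat(sprintf("polar_calibration: I0 = %.4g, zeta = %.4g deg, eta = %.4g deg, b = %.4g\n",
              x$I0, x$zeta_deg, x$eta_deg, x$b))
  if (!is.null(x$se))
    cat("  se:", paste(sprintf("%s = %.3g", names(x$se), x$se), collapse = ", "), "\n")
  invisible(x)
}

#' Channel intensities for a given rod orientation
#'
#' Evaluates the two-channel intensity model at in-plane orientation
#' \code{theta}.
#'
#' @param theta rod orientation (radians), may be a vector.
#' @param cal a [polar_calibration] object.
#' @return a data.frame with columns \code{i_bottom}, \code{i_upper} (counts).
#' @export
intensity_pair <- function(theta, cal) {
  stopifnot(inherits(cal, "polar_calibration"))
  a <- theta + cal$zeta
  env <- cal$I0 * cos(a)^2
  data.frame(i_bottom = env * cos(a - cal$eta)^2 + cal$b,
             i_upper  = env * cos(a - cal$eta + pi / 2)^2 + cal$b)
}

#' Degree of polarization
#'
#' \code{(i_bottom - i_upper) / (i_bottom + i_upper)}; antisymmetric under
#' channel swap and bounded in \code{[-1, 1]} for non-negative intensities.
#'
#' @param i_bottom,i_upper channel intensities (counts); \code{i_bottom} may
#'   also be a data.frame holding both columns.
#' @return the DOP; \code{NA} where the summed intensity is zero.
#' @export
dop <- function(i_bottom, i_upper = NULL) {
  if (is.data.frame(i_bottom)) {
    i_upper <- i_bottom$i_upper
    i_bottom <- i_bottom$i_bottom
  }
  tot <- i_bottom + i_upper
  out <- (i_bottom - i_upper) / tot
  out[tot == 0] <- NA_real_
  out
}

# model residuals for the joint two-channel fit; p = (I0, zeta, eta, b)
.cal_residuals <- function(p, theta, i_bottom, i_upper) {
  a <- theta + p[2]
  env <- p[1] * cos(a)^2
  c(env * cos(a - p[3])^2 + p[4] - i_bottom,
    env * sin(a - p[3])^2 + p[4] - i_upper)
}

#' Fit the polarization calibration from an angle sweep
#'
#' Joint nonlinear least squares of the two-channel model on a calibration
#' sweep (polarizer rotated over at least a quarter turn). Initial estimates
#' come from the sum channel (which isolates \code{I0}, \code{zeta} and
#' \code{b} through \code{I0 cos^2(theta + zeta) + 2b}) followed by a coarse
#' grid on \code{eta}; the joint fit is then refined by Levenberg--Marquardt.
#' Phases are identifiable modulo 180 degrees and are reported in
#' \code{[0, 180)}.
#'
#' @param sweep a data.frame with columns \code{angle_deg}, \code{i_bottom},
#'   \code{i_upper}, as produced by [gen_calibration_sweep()].
#' @return a [polar_calibration] with standard errors (\code{se}) from the
#'   fit covariance and attributes \code{rss} (residual sum of squares) and
#'   \code{df_residual}.
#' @export
fit_calibration <- function(sweep) {
  stopifnot(all(c("angle_deg", "i_bottom", "i_upper") %in% names(sweep)))
  theta <- sweep$angle_deg * pi / 180
  ib <- sweep$i_bottom; iu <- sweep$i_upper
  n_distinct <- length(unique(round(sweep$angle_deg %% 180, 6)))
  span <- diff(range(sweep$angle_deg))
  if (n_distinct < 8 || span < 90)
    stop("underdetermined sweep: need >= 8 distinct angles spanning >= 90 degrees")

  # initialization from the sum channel: sum = I0/2 (1 + cos(2 theta + 2 zeta)) + 2b
  s <- ib + iu
  X <- cbind(1, cos(2 * theta), sin(2 * theta))
  cf <- stats::lm.fit(X, s)$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  zeta0 <- (atan2(-cf[3], cf[2]) / 2) %% pi
  I00 <- max(2 * amp, 1e-6)
  b0 <- max((cf[1] - amp) / 2, 0)
  etas <- seq(0, pi, length.out = 73)[-73]
  sse <- vapply(etas, function(e)
    sum(.cal_residuals(c(I00, zeta0, e, b0), theta, ib, iu)^2), 0)
  eta0 <- etas[which.min(sse)]

  fit <- minpack.lm::nls.lm(par = c(I00, zeta0, eta0, b0),
                            fn = .cal_residuals,
                            theta = theta, i_bottom = ib, i_upper = iu,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  if (fit$info == 0 || fit$info == 5) {
    stop(sprintf(
      "calibration fit did not converge (info = %d); residual RMS = %.3g",
      fit$info, sqrt(mean(fit$fvec^2))))
  }
  p <- unname(fit$par)
  if (p[1] < 0) {        # amplitude sign ambiguity never occurs off degenerate data
    p[1] <- abs(p[1])
  }
  p[2] <- p[2] %% pi
  p[3] <- p[3] %% pi
  dof <- 2 * length(theta) - 4
  sigma2 <- sum(fit$fvec^2) / max(dof, 1)
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (!is.null(covm)) {
    s <- sqrt(pmax(diag(covm), 0))
    c(I0 = s[1], zeta_deg = s[2] * 180 / pi, eta_deg = s[3] * 180 / pi, b = s[4])
  } else NULL
  out <- polar_calibration(I0 = p[1], zeta_deg = p[2] * 180 / pi,
                           eta_deg = p[3] * 180 / pi, b = max(p[4], 0), se = se)
  attr(out, "rss") <- sum(fit$fvec^2)
  attr(out, "df_residual") <- dof
  out
}

#' Invert a channel-intensity pair to the rod orientation
#'
#' Finds the orientation \code{theta} in \code{[0, 180)} degrees whose model
#' intensities best match an observed pair, by a coarse grid (0.5 degree)
#' followed by local golden-section refinement. The inversion is undefined
#' when the pair carries no signal above background (rod near the optical
#' null): such calls return \code{NA} with \code{defined = FALSE}.
#'
#' @param i_bottom,i_upper observed channel intensities (counts).
#' @param cal a [polar_calibration].
#' @param min_signal minimum background-subtracted summed intensity, as a
#'   fraction of \code{I0}, below which the angle is flagged undefined
#'   (default 1e-3).
#' @return a data.frame with columns \code{angle_deg}, \code{residual} (root
#'   sum of squared intensity misfit) and \code{defined}.
#' @export
estimate_angle <- function(i_bottom, i_upper, cal, min_signal = 1e-3) {
  stopifnot(inherits(cal, "polar_calibration"))
  n <- length(i_bottom)
  grid <- seq(0, pi, by = 0.5 * pi / 180)
  grid <- grid[-length(grid)]
  mod <- intensity_pair(grid, cal)
  out <- data.frame(angle_deg = rep(NA_real_, n), residual = NA_real_,
                    defined = FALSE)
  for (k in seq_len(n)) {
    if ((i_bottom[k] - cal$b) + (i_upper[k] - cal$b) < min_signal * cal$I0) next
    ssr <- (mod$i_bottom - i_bottom[k])^2 + (mod$i_upper - i_upper[k])^2
    i <- which.min(ssr)
    lo <- grid[i] - 0.5 * pi / 180
    hi <- grid[i] + 0.5 * pi / 180
    f <- function(th) {
      m <- intensity_pair(th, cal)
      (m$i_bottom - i_bottom[k])^2 + (m$i_upper - i_upper[k])^2
    }
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-10)
    out$angle_deg[k] <- (opt$minimum %% pi) * 180 / pi
    out$residual[k] <- sqrt(opt$objective)
    out$defined[k] <- TRUE
  }
  out
}

#' Invert an intensity time series with temporal continuity
#'
#' Per-frame inversion as in [estimate_angle()], but near-degenerate minima
#' (intensity pairs mapping to two orientations with comparable residual) are
#' resolved by picking the candidate closest, modulo 180 degrees, to the last
#' defined angle. The first defined frame takes the smaller angle.
#'
#' @inheritParams estimate_angle
#' @param tie_tol residual ratio under which two local minima count as
#'   degenerate (default 1.5).
#' @return as [estimate_angle()].
#' @export
estimate_angle_series <- function(i_bottom, i_upper, cal,
                                  min_signal = 1e-3, tie_tol = 1.5) {
  stopifnot(inherits(cal, "polar_calibration"))
  n <- length(i_bottom)
  step <- 0.5 * pi / 180
  grid <- seq(0, pi - step / 2, by = step)
  mod <- intensity_pair(grid, cal)
  ng <- length(grid)
  out <- data.frame(angle_deg = rep(NA_real_, n), residual = NA_real_,
                    defined = FALSE)
  prev <- NA_real_
  refine <- function(i, ib, iu) {
    f <- function(th) {
      m <- intensity_pair(th, cal)
      (m$i_bottom - ib)^2 + (m$i_upper - iu)^2
    }
    stats::optimize(f, c(grid[i] - step, grid[i] + step), tol = 1e-10)
  }
  for (k in seq_len(n)) {
    if (is.na(i_bottom[k]) || is.na(i_upper[k])) next
    if ((i_bottom[k] - cal$b) + (i_upper[k] - cal$b) < min_signal * cal$I0) next
    ssr <- (mod$i_bottom - i_bottom[k])^2 + (mod$i_upper - i_upper[k])^2
    # local minima on the circular grid
    lft <- ssr[c(ng, seq_len(ng - 1))]
    rgt <- ssr[c(seq_len(ng)[-1], 1)]
    locs <- which(ssr <= lft & ssr <= rgt)
    best <- min(ssr[locs])
    cand <- locs[ssr[locs] <= tie_tol * best + 1e-300]
    opts <- lapply(cand, refine, ib = i_bottom[k], iu = i_upper[k])
    angs <- vapply(opts, function(o) o$minimum %% pi, 0)
    objs <- vapply(opts, function(o) o$objective, 0)
    pick <- if (length(angs) == 1) 1L
    else if (is.na(prev)) which.min(angs + 1e6 * (objs > tie_tol * min(objs)))
    else {
      d <- abs(angs - prev) %% pi
      d <- pmin(d, pi - d)
      which.min(d + 1e6 * (objs > tie_tol * min(objs)))
    }
    out$angle_deg[k] <- angs[pick] * 180 / pi
    out$residual[k] <- sqrt(objs[pick])
    out$defined[k] <- TRUE
    prev <- angs[pick]
  }
  out
}

#' Direct least-squares ellipse fit of the DOP--intensity loop
#'
#' As the rod rotates through 180 degrees, the point (summed intensity, DOP)
#' traces a closed conic, which for the two-channel model is exactly an
#' ellipse. This fits the general conic \code{a x^2 + b x y + c y^2 + d x +
#' e y + f = 0} by the direct (algebraic, ellipse-constrained) least-squares
#' method: the quadratic coefficients are obtained from a 3x3 generalized
#' eigenproblem under the constraint \code{4ac - b^2 = 1}, which guarantees an
#' ellipse without initialization.
#'
#' @param sum_intensity summed-intensity series (counts).
#' @param dop_series DOP series.
#' @return a list with \code{center} (x, y), \code{axes} (semi-major,
#'   semi-minor), \code{tilt_deg}, \code{coefficients} (a--f), \code{rms}
#'   (root-mean-square algebraic distance at unit quadratic norm) and
#'   \code{coverage}, the fraction of the ellipse's angular range visited by
#'   the data (1 means the full closed loop, the signature of continuous
#'   polarization rotation).
#' @export
fit_dop_ellipse <- function(sum_intensity, dop_series) {
  ok <- is.finite(sum_intensity) & is.finite(dop_series)
  x <- sum_intensity[ok]; y <- dop_series[ok]
  if (length(x) < 5) stop("ellipse fit needs >= 5 finite points")
  # scale to unit box for conditioning
  mx <- mean(x); my <- mean(y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("degenerate (collinear) points: no ellipse")
  xs <- (x - mx) / sx; ys <- (y - my) / sy
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T1
  # constraint 4ac - b^2 = 1: premultiply by inverse constraint matrix
  Mc <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(Mc)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  i <- which(cond > 0)
  if (length(i) == 0) stop("degenerate points: no ellipse solution")
  a1 <- evec[, i[1]]   # exactly one eigenvector satisfies the ellipse constraint
  a1 <- a1 / sqrt(4 * a1[1] * a1[3] - a1[2]^2)
  coefs_s <- c(a1, as.vector(T1 %*% a1))
  # un-scale conic coefficients back to data units
  A <- coefs_s[1] / sx^2
  B <- coefs_s[2] / (sx * sy)
  C <- coefs_s[3] / sy^2
  D <- coefs_s[4] / sx - 2 * coefs_s[1] * mx / sx^2 - coefs_s[2] * my / (sx * sy)
  E <- coefs_s[5] / sy - 2 * coefs_s[3] * my / sy^2 - coefs_s[2] * mx / (sx * sy)
  F <- coefs_s[6] - coefs_s[4] * mx / sx - coefs_s[5] * my / sy +
    coefs_s[1] * mx^2 / sx^2 + coefs_s[2] * mx * my / (sx * sy) +
    coefs_s[3] * my^2 / sy^2
  cf <- c(A, B, C, D, E, F)
  cf <- cf / sqrt(sum(cf[1:3]^2))
  det2 <- 4 * cf[1] * cf[3] - cf[2]^2
  xc <- (cf[2] * cf[5] - 2 * cf[3] * cf[4]) / det2
  yc <- (cf[2] * cf[4] - 2 * cf[1] * cf[5]) / det2
  # axes from the quadratic form eigenvalues
  Fc <- cf[1] * xc^2 + cf[2] * xc * yc + cf[3] * yc^2 + cf[4] * xc +
    cf[5] * yc + cf[6]
  Q <- matrix(c(cf[1], cf[2] / 2, cf[2] / 2, cf[3]), 2, 2)
  eQ <- eigen(Q, symmetric = TRUE)
  ax <- sqrt(pmax(-Fc / eQ$values, 0))
  tilt <- atan2(eQ$vectors[2, which.max(ax)], eQ$vectors[1, which.max(ax)])
  vals <- cf[1] * x^2 + cf[2] * x * y + cf[3] * y^2 + cf[4] * x + cf[5] * y + cf[6]
  # coverage: fraction of 10-degree bins of the eccentric anomaly that hold data
  ax_s <- sort(ax, decreasing = TRUE)
  ct <- cos(tilt); st <- sin(tilt)
  xr <- ((x - xc) * ct + (y - yc) * st) / max(ax_s[1], 1e-12)
  yr <- (-(x - xc) * st + (y - yc) * ct) / max(ax_s[2], 1e-12)
  bins <- unique(floor(((atan2(yr, xr) + pi) / (2 * pi)) * 36))
  list(center = c(x = xc, y = yc),
       axes = ax_s,
       tilt_deg = (tilt * 180 / pi) %% 180,
       coefficients = cf,
       rms = sqrt(mean(vals^2)),
       coverage = length(bins) / 36)
}
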