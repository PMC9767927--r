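# Localization of the two polarization spots in dark-field image stacks.
# Images are matrices indexed [row, col] = [y, x]; subpixel positions are in
# pixel units with the centre of pixel (1,1) at (1,1).

#' Astigmatism Z calibration
#'
#' Converts the ratio of fitted Gaussian widths \code{s_y / s_x} (imprinted by
#' the cylindrical lens) into a Z displacement:
#' \code{Z = factor * (s_y/s_x - ratio_at_focus)}.
#'
#' @param factor micrometres per unit width ratio (default 0.98).
#' @param ratio_at_focus width ratio at focus (default 1).
#' @return an object of class \code{z_calibration}.
#' @export
z_calibration <- function(factor = 0.98, ratio_at_focus = 1) {
  stopifnot(factor != 0)
  structure(list(factor = factor, ratio_at_focus = ratio_at_focus),
            class = "z_calibration")
}

#' Z position from astigmatic spot widths
#'
#' @param s_x,s_y fitted Gaussian SDs along X and Y (same units).
#' @param zcal a [z_calibration].
#' @return Z displacement in micrometres (positive where \code{s_y > s_x} at
#'   the default calibration).
#' @export
z_from_astigmatism <- function(s_x, s_y, zcal = z_calibration()) {
  stopifnot(inherits(zcal, "z_calibration"), all(s_x > 0))
  zcal$factor * (s_y / s_x - zcal$ratio_at_focus)
}

#' Fit an axis-aligned elliptical 2D Gaussian to an image patch
#'
#' Model: \code{A exp(-(x-x0)^2/(2 s_x^2) - (y-y0)^2/(2 s_y^2)) + offset},
#' fitted by Levenberg--Marquardt with moment-based initial estimates. The
#' Gaussian axes are the camera axes, matching the astigmatic width-ratio
#' readout.
#'
#' @param patch numeric matrix (rows = y, cols = x), at least 7x7.
#' @param init optional named list/vector with any of \code{x0, y0, s_x, s_y,
#'   amplitude, offset} to override the moment-based start.
#' @return a list (class \code{spot_fit}) with \code{x}, \code{y} (subpixel,
#'   patch coordinates), \code{s_x}, \code{s_y}, \code{amplitude},
#'   \code{offset}, \code{integrated} (\code{2 pi A s_x s_y}), \code{rss} and
#'   \code{converged}. Fits that end on the patch border, with non-positive
#'   amplitude or width, or without signal are flagged
#'   \code{converged = FALSE}.
#' @export
fit_gaussian_2d <- function(patch, init = NULL) {
  stopifnot(is.matrix(patch), nrow(patch) >= 7, ncol(patch) >= 7)
  ny <- nrow(patch); nx <- ncol(patch)
  failed <- function() {
    structure(list(x = NA_real_, y = NA_real_, s_x = NA_real_, s_y = NA_real_,
                   amplitude = NA_real_, offset = NA_real_,
                   integrated = NA_real_, rss = NA_real_, converged = FALSE),
              class = "spot_fit")
  }
  off0 <- stats::median(patch[c(1, ny), ]) / 2 + stats::median(patch[, c(1, nx)]) / 2
  w <- pmax(patch - off0, 0)
  tot <- sum(w)
  if (tot <= 0 || max(patch) - min(patch) <= .Machine$double.eps * 10)
    return(failed())
  xs <- col(patch); ys <- row(patch)
  x0 <- sum(w * xs) / tot; y0 <- sum(w * ys) / tot
  sx0 <- sqrt(max(sum(w * (xs - x0)^2) / tot, 0.25))
  sy0 <- sqrt(max(sum(w * (ys - y0)^2) / tot, 0.25))
  p0 <- c(A = max(patch) - off0, x0 = x0, y0 = y0, sx = sx0, sy = sy0,
          off = off0)
  if (!is.null(init)) {
    init <- unlist(init)
    map <- c(amplitude = "A", x0 = "x0", y0 = "y0", s_x = "sx", s_y = "sy",
             offset = "off")
    for (nm in names(init)) if (nm %in% names(map)) p0[map[[nm]]] <- init[[nm]]
  }
  resid_fn <- function(p) {
    as.vector(p[1] * exp(-(xs - p[2])^2 / (2 * p[4]^2) -
                           (ys - p[3])^2 / (2 * p[5]^2)) + p[6] - patch)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  p <- fit$par
  ok <- fit$info %in% 1:4 &&
    p[1] > 0 && p[4] > 0 && p[5] > 0 &&
    p[2] > 1 && p[2] < nx && p[3] > 1 && p[3] < ny
  if (!ok) return(failed())
  structure(list(x = unname(p[2]), y = unname(p[3]),
                 s_x = unname(abs(p[4])), s_y = unname(abs(p[5])),
                 amplitude = unname(p[1]), offset = unname(p[6]),
                 integrated = unname(2 * pi * p[1] * abs(p[4]) * abs(p[5])),
                 rss = sum(fit$fvec^2), converged = TRUE),
            class = "spot_fit")
}

#' Centred moving average with truncated ends
#'
#' Boxcar smoother used before cycle detection. Near the series ends the
#' window is truncated to the available samples (no padding, no phantom
#' values); the output length equals the input length.
#'
#' @param series numeric vector (NAs are ignored within each window).
#' @param window odd window length (default 15 frames).
#' @return the smoothed series.
#' @export
moving_average <- function(series, window = 15) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(series)
  if (window > n) stop("window longer than series")
  h <- (window - 1) / 2
  v <- ifelse(is.na(series), 0, series)
  m <- as.numeric(!is.na(series))
  cs <- c(0, cumsum(v)); cm <- c(0, cumsum(m))
  lo <- pmax(seq_len(n) - h, 1); hi <- pmin(seq_len(n) + h, n)
  cnt <- cm[hi + 1] - cm[lo]
  out <- (cs[hi + 1] - cs[lo]) / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Track a particle through a two-spot polarization image stack
#'
#' Each frame holds the two displacer-separated polarization spots of one
#' particle: the upper spot displaced by \code{-offset/2} and the bottom spot
#' by \code{+offset/2} along the camera Y (row) axis. Both spots are fitted
#' with [fit_gaussian_2d()]; the particle X/Y is the mean of the two spot
#' positions (which cancels the symmetric displacer offset), Z comes from the
#' amplitude-weighted mean astigmatic width ratio, and the channel
#' intensities are the integrated Gaussian volumes. Frames where either fit
#' fails are flagged (\code{ok = FALSE}) and never interpolated.
#'
#' @param stack numeric array \code{[row, col, frame]} or list of matrices.
#' @param displacer_offset spot separation along camera Y, in pixels.
#' @param zcal a [z_calibration].
#' @param pixel_size_nm pixel size (nm), default 42.
#' @param frame_rate frames per second (default 100), used for the time axis.
#' @param patch_half half-size of the square fit patch (default 6 px).
#' @return a track data.frame (see [write_track()] for the schema) with an
#'   extra logical column \code{ok}; positions in micrometres relative to the
#'   first frame's fitted position are in \code{x_um,y_um,z_um} and raw pixel
#'   positions in attributes \code{x_px,y_px}.
#' @export
track_stack <- function(stack, displacer_offset, zcal = z_calibration(),
                        pixel_size_nm = 42, frame_rate = 100,
                        patch_half = 6) {
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(length(dim(stack)) == 3)
  nf <- dim(stack)[3]
  res <- data.frame(frame = seq_len(nf) - 1L)
  res$t <- res$frame / frame_rate
  res$x_px <- res$y_px <- res$z_um <- NA_real_
  res$i_bottom <- res$i_upper <- NA_real_
  res$ok <- FALSE
  prev <- NULL
  for (f in seq_len(nf)) {
    img <- stack[, , f]
    cts <- .locate_spot_pair(img, displacer_offset, prev)
    fits <- lapply(cts, function(ct)
      .fit_at(img, ct, patch_half))
    up <- fits$upper; bo <- fits$bottom
    if (is.null(up) || is.null(bo) || !up$converged || !bo$converged) next
    # positions in full-image pixel coordinates
    res$x_px[f] <- (up$x + bo$x) / 2
    res$y_px[f] <- (up$y + bo$y) / 2
    wsum <- up$amplitude + bo$amplitude
    ratio <- (up$amplitude * (up$s_y / up$s_x) +
                bo$amplitude * (bo$s_y / bo$s_x)) / wsum
    res$z_um[f] <- zcal$factor * (ratio - zcal$ratio_at_focus)
    res$i_upper[f] <- up$integrated
    res$i_bottom[f] <- bo$integrated
    res$ok[f] <- TRUE
    prev <- list(upper = c(up$x, up$y), bottom = c(bo$x, bo$y))
  }
  ref <- which(res$ok)[1]
  if (is.na(ref)) stop("no frame produced two converged spot fits")
  out <- data.frame(frame = res$frame, t = res$t,
                    x_um = (res$x_px - res$x_px[ref]) * pixel_size_nm / 1000,
                    y_um = (res$y_px - res$y_px[ref]) * pixel_size_nm / 1000,
                    z_um = res$z_um,
                    i_bottom = res$i_bottom, i_upper = res$i_upper,
                    dop = dop(res$i_bottom, res$i_upper),
                    angle_deg = NA_real_, angle_defined = 0L,
                    ok = res$ok)
  attr(out, "x_px") <- res$x_px
  attr(out, "y_px") <- res$y_px
  out
}

# find approximate centres of the upper/bottom spots; `prev` carries the
# previous frame's positions as a starting guess
.locate_spot_pair <- function(img, displacer_offset, prev = NULL) {
  if (!is.null(prev)) return(prev)
  sm <- img
  i1 <- which(sm == max(sm), arr.ind = TRUE)[1, ]
  # mask a neighbourhood of the first maximum, then find the second
  r <- max(3, round(displacer_offset / 3))
  rows <- pmax(1, i1[1] - r):pmin(nrow(sm), i1[1] + r)
  sm[rows, pmax(1, i1[2] - r):pmin(ncol(sm), i1[2] + r)] <- -Inf
  i2 <- which(sm == max(sm), arr.ind = TRUE)[1, ]
  a <- c(i1[2], i1[1]); b <- c(i2[2], i2[1])       # (x, y)
  if (a[2] >= b[2]) list(upper = b, bottom = a) else list(upper = a, bottom = b)
}

.fit_at <- function(img, center_xy, patch_half) {
  cx <- round(center_xy[1]); cy <- round(center_xy[2])
  rows <- (cy - patch_half):(cy + patch_half)
  cols <- (cx - patch_half):(cx + patch_half)
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > nrow(img) ||
      max(cols) > ncol(img)) {
    rows <- pmax(pmin(rows, nrow(img)), 1)
    cols <- pmax(pmin(cols, ncol(img)), 1)
    rows <- unique(rows); cols <- unique(cols)
    if (length(rows) < 7 || length(cols) < 7) return(NULL)
  }
  ft <- fit_gaussian_2d(img[rows, cols])
  if (ft$converged) {
    ft$x <- ft$x + cols[1] - 1
    ft$y <- ft$y + rows[1] - 1
  }
  ft
}
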