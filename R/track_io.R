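# Track CSV schema, calibration JSON, run manifests and the command-line
# entry points tying the stages into small pipelines.

.track_columns <- c("frame", "t", "x_um", "y_um", "z_um", "i_bottom",
                    "i_upper", "dop", "angle_deg", "angle_defined")

#' Write / read a track table as CSV
#'
#' The canonical track schema: \code{frame} (int, strictly increasing),
#' \code{t} (s), \code{x_um, y_um, z_um}, \code{i_bottom, i_upper} (counts),
#' \code{dop}, \code{angle_deg} (in [0, 180), NA where undefined) and
#' \code{angle_defined} (0/1). Reading validates the header, frame
#' monotonicity, and that the stored DOP agrees with the intensities (a
#' mismatch beyond 1e-6 warns).
#'
#' @param track a track data.frame.
#' @param path CSV file path.
#' @return \code{read_track} returns the validated data.frame.
#' @export
write_track <- function(track, path) {
  miss <- setdiff(.track_columns, names(track))
  if (length(miss) > 0)
    stop("track is missing columns: ", paste(miss, collapse = ", "))
  utils::write.csv(track[, .track_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(.track_columns, names(tab))
  if (length(miss) > 0)
    stop("track file missing columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(.track_columns, c("frame", "angle_defined")))
    tab[[col]] <- as.numeric(tab[[col]])   # all-NA columns parse as logical
  tab$frame <- as.integer(tab$frame)
  tab$angle_defined <- as.integer(tab$angle_defined)
  bad <- which(diff(tab$frame) <= 0)
  if (length(bad) > 0)
    stop(sprintf("frames not strictly increasing at line %d", bad[1] + 2L))
  ok <- is.finite(tab$i_bottom) & is.finite(tab$i_upper) & is.finite(tab$dop)
  if (any(ok)) {
    re <- dop(tab$i_bottom[ok], tab$i_upper[ok])
    if (any(abs(re - tab$dop[ok]) > 1e-6, na.rm = TRUE))
      warning("stored dop column inconsistent with intensities (> 1e-6)")
  }
  tab
}

#' Write / read a polarization calibration as JSON
#'
#' Keys: \code{I0}, \code{zeta_deg}, \code{eta_deg}, \code{b}, plus \code{se}
#' when present.
#'
#' @param cal a [polar_calibration].
#' @param path JSON file path.
#' @return \code{read_calibration} returns a [polar_calibration].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "polar_calibration"))
  x <- list(I0 = cal$I0, zeta_deg = cal$zeta_deg, eta_deg = cal$eta_deg,
            b = cal$b)
  if (!is.null(cal$se)) x$se <- as.list(cal$se)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  polar_calibration(x$I0, x$zeta_deg, x$eta_deg, x$b,
                    se = if (!is.null(x$se)) unlist(x$se) else NULL)
}

#' Write a run manifest next to an output file
#'
#' Records the command, parameters, seed and package version so every output
#' is reproducible from its sidecar.
#'
#' @param out_path the output the manifest describes; the manifest lands at
#'   \code{<out_path>.manifest.json}.
#' @param command command or function name.
#' @param params named list of parameters (coerced to JSON).
#' @param seed the RNG seed used.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(out_path, command, params, seed) {
  man <- list(command = command, params = params, seed = seed,
              package = "gnrtrack",
              version = as.character(utils::packageVersion("gnrtrack")))
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- command-line interface -------------------------------------------------

.cli_opts <- function(args) {
  # parse --key value pairs (and --flag for logicals)
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[[i + 1]], "--")) {
      out[[key]] <- args[[i + 1]]
      i <- i + 2
    } else {
      out[[key]] <- TRUE
      i <- i + 1
    }
  }
  out
}

.cli_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) {
    if (is.null(default)) stop("missing required option --", key)
    default
  } else as.numeric(opts[[key]])
}

.cli_need_out <- function(opts) {
  if (is.null(opts$out)) stop("missing required option --out")
  opts$out
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands. Every command takes \code{--seed}
#' and \code{--out}, writes deterministic output for a given seed, and drops
#' a \code{.manifest.json} sidecar next to the output. Invoke from a shell
#' via the script in \code{inst/cli/gnrtrack.R}, or call directly with an
#' argument vector.
#'
#' Commands: \describe{
#'   \item{simulate-track}{\code{--v --pitch --phi --yaw-sign --duration
#'     --intensity-sd --localization-sd --seed --out} writes the noisy track
#'     CSV and a \code{.truth.csv} sidecar.}
#'   \item{calibrate}{\code{--sweep <csv> --out <json>} fits the calibration
#'     from a sweep table, or with \code{--simulate} generates and fits one.}
#'   \item{analyze-track}{\code{--track <csv> [--cal <json>] --out <json>}
#'     writes the per-track report.}
#'   \item{ratchet-scan}{\code{--alpha --gamma [--dmax --step] --out <csv>}.}
#'   \item{cargo-sim}{\code{--ticks [--t-step --n-motors --seed] --out <csv>}
#'     writes the pose trace plus a summary JSON sidecar.}
#'   \item{mechanics}{\code{--what twist|capacity|yaw --out <json>}.}
#'   \item{simulate-images}{\code{--v --pitch --duration --snr --seed
#'     --out <tiff>} renders a synthetic stack with truth sidecar.}
#' }
#'
#' @param args character vector of command-line arguments (the first element
#'   is the subcommand).
#' @return invisibly, the main output path.
#' @export
gnr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) stop("usage: gnrtrack <command> [--options]")
  cmd <- args[[1]]
  opts <- .cli_opts(args[-1])
  seed <- as.integer(.cli_num(opts, "seed", 1))
  out <- .cli_need_out(opts)
  switch(cmd,
    "simulate-track" = {
      gt <- ground_truth(
        model = motion_model(v = .cli_num(opts, "v", 0.5),
                             pitch_um = .cli_num(opts, "pitch", 0.7),
                             phi = .cli_num(opts, "phi", 0) * pi / 180,
                             yaw_sign = .cli_num(opts, "yaw-sign", -1)),
        duration = .cli_num(opts, "duration", 6), seed = seed)
      ns <- noise_spec(intensity_sd = .cli_num(opts, "intensity-sd", 3),
                       localization_sd = .cli_num(opts, "localization-sd", 10))
      tk <- gen_track(gt, ns)
      write_track(tk$noisy, out)
      write_track(tk$truth, paste0(sub("\\.csv$", "", out), ".truth.csv"))
      write_manifest(out, cmd, c(opts, list()), seed)
    },
    "calibrate" = {
      sweep <- if (isTRUE(opts$simulate)) {
        gen_calibration_sweep(polar_calibration(127.5, 99.3, 45.3, 19.5),
                              noise = noise_spec(intensity_sd =
                                                   .cli_num(opts, "intensity-sd", 0)),
                              seed = seed)
      } else {
        if (is.null(opts$sweep)) stop("missing --sweep (or --simulate)")
        utils::read.csv(opts$sweep)
      }
      write_calibration(fit_calibration(sweep), out)
      write_manifest(out, cmd, opts, seed)
    },
    "analyze-track" = {
      if (is.null(opts$track)) stop("missing --track")
      track <- read_track(opts$track)
      cal <- if (!is.null(opts$cal)) read_calibration(opts$cal)
      else polar_calibration(127.5, 99.3, 45.3, 19.5)
      rep <- analyze_track(track, cal)
      jsonlite::write_json(list(
        velocity_um_s = rep$velocity_um_s,
        helix_pitch_um = rep$helix_pitch$mean,
        helix_pitch_sd = rep$helix_pitch$sd,
        helix_cycles = rep$helix_pitch$n,
        polarization_pitch_um = rep$polarization_pitch$mean,
        polarization_pitch_sd = rep$polarization_pitch$sd,
        polarization_cycles = rep$polarization_pitch$n,
        pearson_r = rep$pearson_r,
        yaw_direction = rep$direction),
        out, auto_unbox = TRUE, digits = NA)
      write_manifest(out, cmd, opts, seed)
    },
    "ratchet-scan" = {
      sc <- ratchet_scan(.cli_num(opts, "alpha"), .cli_num(opts, "gamma"),
                         d_max = .cli_num(opts, "dmax", 0.995),
                         step = .cli_num(opts, "step", 0.005))
      utils::write.csv(sc, out, row.names = FALSE)
      write_manifest(out, cmd, opts, seed)
    },
    "cargo-sim" = {
      p <- sim_params(n_motors = .cli_num(opts, "n-motors", 13),
                      t_step = .cli_num(opts, "t-step", 0), seed = seed)
      r <- cargo_run(p, n_ticks = as.integer(.cli_num(opts, "ticks", 10000)))
      utils::write.csv(r$trace, out, row.names = FALSE)
      jsonlite::write_json(c(r$summary, as.list(r$counts)),
                           paste0(out, ".summary.json"),
                           auto_unbox = TRUE, digits = NA)
      write_manifest(out, cmd, opts, seed)
    },
    "mechanics" = {
      what <- if (is.null(opts$what)) "twist" else opts$what
      res <- switch(what,
        twist = twist_angle(),
        capacity = surface_capacity(),
        yaw = list(degrees_per_step = yaw_per_step(
          .cli_num(opts, "pitch-nm", 700), .cli_num(opts, "step-nm", 8))),
        stop("unknown --what: ", what))
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
      write_manifest(out, cmd, opts, seed)
    },
    "simulate-images" = {
      gt <- ground_truth(model = motion_model(v = .cli_num(opts, "v", 0.5),
                                              pitch_um = .cli_num(opts, "pitch", 0.7)),
                         duration = .cli_num(opts, "duration", 1), seed = seed)
      tk <- gen_track(gt, noise_spec(intensity_sd = 0, localization_sd = 0))
      st <- gen_image_stack(tk$truth, noise = noise_spec(
        intensity_sd = .cli_num(opts, "noise-sd", 0.05), background = 1),
        seed = seed)
      write_stack(st$stack, out)
      utils::write.csv(st$truth, paste0(out, ".truth.csv"), row.names = FALSE)
      write_manifest(out, cmd, opts, seed)
    },
    stop("unknown command: ", cmd))
  invisible(out)
}
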