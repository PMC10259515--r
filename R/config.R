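#' Analysis run configuration
#'
#' Bundles the acquisition and analysis constants shared across the pipeline.
#' Times are minutes, lengths micrometres, angles degrees.
#'
#' @param unit_scale micrometres per input coordinate unit. Inputs already in
#'   micrometres use 1; pixel inputs must supply the pixel size. No default is
#'   assumed for the pixel size of any particular microscope, so this argument
#'   is required.
#' @param frame_interval_s acquisition interval between frames, seconds.
#' @param max_observation_min observation cap; tracked rows beyond this time
#'   are dropped at read time.
#' @param pre_division_frames frames retained before the progenitor division
#'   in segmentation exports.
#' @param post_division_frames_min minimum frames required after division.
#' @param critical_angle_deg inversion criterion: a pair inverts iff its final
#'   absolute cumulative angle strictly exceeds this value.
#' @param noise_frame_cap number of leading frames used for the trajectory
#'   noise statistic.
#' @param min_displacement_um pairs in which either cell's net displacement
#'   (start-to-end chord) is below this are excluded from the noise statistic.
#' @param noise_aggregation how the two cells' path/chord ratios are pooled:
#'   `"pooled"` divides the summed paths by the summed chords; `"mean"`
#'   averages the per-cell ratios.
#' @param seed integer seed recorded in result manifests.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(unit_scale,
                       frame_interval_s = 200,
                       max_observation_min = 500,
                       pre_division_frames = 10,
                       post_division_frames_min = 70,
                       critical_angle_deg = 90,
                       noise_frame_cap = 200,
                       min_displacement_um = 2,
                       noise_aggregation = c("pooled", "mean"),
                       seed = NULL) {
  if (missing(unit_scale)) {
    stop("unit_scale (micrometres per coordinate unit) is required", call. = FALSE)
  }
  noise_aggregation <- match.arg(noise_aggregation)
  stopifnot(
    is.numeric(unit_scale), length(unit_scale) == 1, unit_scale > 0,
    frame_interval_s > 0, max_observation_min > 0,
    pre_division_frames >= 0, post_division_frames_min > 0,
    critical_angle_deg > 0, critical_angle_deg < 180,
    noise_frame_cap >= 2, min_displacement_um >= 0
  )
  structure(
    list(
      unit_scale = unit_scale,
      frame_interval_s = frame_interval_s,
      max_observation_min = max_observation_min,
      pre_division_frames = pre_division_frames,
      post_division_frames_min = post_division_frames_min,
      critical_angle_deg = critical_angle_deg,
      noise_frame_cap = noise_frame_cap,
      min_displacement_um = min_displacement_um,
      noise_aggregation = noise_aggregation,
      seed = seed
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml`/`.json`).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}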