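#' Inversion classification
#'
#' A pair performs a planar cell inversion iff its final absolute cumulative
#' angle strictly exceeds the critical angle (default 90 degrees); a final
#' turn of exactly the critical angle is a local rearrangement, not an
#' inversion.
#'
#' @param series an [angle_series()].
#' @param critical_angle_deg inversion threshold in degrees.
#' @return logical flag.
#' @export
classify_inversion <- function(series, critical_angle_deg = 90) {
  stopifnot(inherits(series, "angle_series"))
  abs(tail(series$cum_deg, 1)) > critical_angle_deg
}

#' Starting and final positional angles
#'
#' Circular (unit-vector) means of the first and last `k` positional angles.
#' Series shorter than `k` use all observations and set the `short` flag.
#'
#' @param series an [angle_series()].
#' @param k number of observations averaged at each end (default 10).
#' @return list with `starting_angle_deg`, `final_angle_deg`, `short`.
#' @export
start_final_angles <- function(series, k = 10) {
  stopifnot(inherits(series, "angle_series"))
  n <- nrow(series)
  kk <- min(k, n)
  list(
    starting_angle_deg = circular_mean_deg(head(series$alpha_deg, kk)),
    final_angle_deg = circular_mean_deg(tail(series$alpha_deg, kk)),
    short = n < k
  )
}

#' Overshoot of a rotation
#'
#' Difference between the maximal turn (maximal absolute cumulative angle)
#' reached anywhere along the trajectory and the final turn; zero for
#' monotone rotations that hold their end position.
#'
#' @param series an [angle_series()].
#' @return overshoot in degrees (>= 0).
#' @export
overshoot <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  max(series$turn_deg) - tail(series$turn_deg, 1)
}

#' Wobbling of a rotation
#'
#' Arc length (sum of absolute per-frame angle changes) minus the final turn:
#' the small recurrent swings superimposed on the net rotation. Zero iff the
#' angular trajectory is monotone.
#'
#' @param series an [angle_series()].
#' @return wobbling in degrees (>= 0).
#' @export
wobbling <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  tail(series$arc_deg, 1) - tail(series$turn_deg, 1)
}

#' Handedness of a rotation
#'
#' Counter-clockwise (`"CCW"`) iff the final cumulative signed angle is
#' positive, clockwise (`"CW"`) iff negative; exactly zero yields `NA` with a
#' tie flag.
#'
#' @param series an [angle_series()].
#' @return list with `handedness` (`"CW"`, `"CCW"` or `NA`) and `tie` flag.
#' @export
handedness <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  fin <- tail(series$cum_deg, 1)
  if (fin > 0) {
    list(handedness = "CCW", tie = FALSE)
  } else if (fin < 0) {
    list(handedness = "CW", tie = FALSE)
  } else {
    list(handedness = NA_character_, tie = TRUE)
  }
}

#' Trajectory noise of a rotating pair
#'
#' For each sibling, the path length (sum of frame-to-frame displacements of
#' the pairwise-centered positions) and the chord (straight start-to-end
#' distance) are computed over the first `frame_cap` frames. Noise is the
#' quotient of path over chord; with the default `"pooled"` aggregation the
#' two cells' paths and chords are summed before dividing, with `"mean"` the
#' per-cell ratios are averaged. Pairs in which either cell's chord is below
#' `min_displacement_um` are excluded rather than reported.
#'
#' @param pair a [cell_pair()]; centered internally if not already.
#' @param frame_cap leading frames used (default 200).
#' @param min_displacement_um exclusion threshold on each cell's net
#'   displacement (default 2).
#' @param aggregation `"pooled"` or `"mean"`.
#' @return list with `noise` (>= 1, or NA when excluded), `excluded`,
#'   `reason`, and per-cell `path_um`, `chord_um`.
#' @export
trajectory_noise <- function(pair, frame_cap = 200, min_displacement_um = 2,
                             aggregation = c("pooled", "mean")) {
  stopifnot(inherits(pair, "cell_pair"))
  aggregation <- match.arg(aggregation)
  if (!pair$centered) pair <- center_pair(pair)
  n <- min(nrow(pair$xy_a), frame_cap)
  path_chord <- function(xy) {
    xy <- xy[seq_len(n), , drop = FALSE]
    steps <- diff(xy)
    list(
      path = sum(sqrt(steps[, 1]^2 + steps[, 2]^2)),
      chord = sqrt(sum((xy[n, ] - xy[1, ])^2))
    )
  }
  a <- path_chord(pair$xy_a)
  b <- path_chord(pair$xy_b)
  out <- list(
    noise = NA_real_, excluded = FALSE, reason = NA_character_,
    path_um = c(a = a$path, b = b$path),
    chord_um = c(a = a$chord, b = b$chord)
  )
  if (min(a$chord, b$chord) < min_displacement_um) {
    out$excluded <- TRUE
    out$reason <- sprintf(
      "net displacement below %g um (chords %.3g, %.3g)",
      min_displacement_um, a$chord, b$chord
    )
    return(out)
  }
  if (a$chord + b$chord <= 0) {
    stop("zero total chord on a non-excluded pair", call. = FALSE)
  }
  out$noise <- if (aggregation == "pooled") {
    (a$path + b$path) / (a$chord + b$chord)
  } else {
    mean(c(a$path / a$chord, b$path / b$chord))
  }
  out
}

#' All scalar rotation metrics for one pair
#'
#' Centers the pair, derives the angle series and assembles the per-pair
#' metrics row: start/final angles, final/maximal turn, overshoot, wobbling,
#' trajectory noise (with exclusion flag), handedness, inversion flag, and -
#' for inverting pairs - the logistic fit with its tangent-intersection phase
#' boundaries, onset (`Ic` minus birth time), duration (`Id - Ic`) and
#' termination (`Id`).
#'
#' @param pair a [cell_pair()].
#' @param config a [run_config()].
#' @return one-row data.frame of class `rotation_metrics`.
#' @export
rotation_metrics <- function(pair, config) {
  stopifnot(inherits(pair, "cell_pair"), inherits(config, "run_config"))
  pair <- center_pair(pair)
  ser <- angle_series(pair)
  sf <- start_final_angles(ser)
  hand <- handedness(ser)
  nz <- trajectory_noise(pair,
    frame_cap = config$noise_frame_cap,
    min_displacement_um = config$min_displacement_um,
    aggregation = config$noise_aggregation
  )
  inv <- classify_inversion(ser, config$critical_angle_deg)
  birth <- attr(ser, "birth_time_min")
  if (is.na(birth)) birth <- ser$time_min[1]

  fit_a <- fit_b <- fit_c <- fit_d <- fit_rms <- NA_real_
  ic <- id <- onset <- duration <- termination <- NA_real_
  fit_failed <- NA
  clamped <- NA
  if (inv) {
    fit <- fit_phase_logistic(ser)
    fit_failed <- !fit$converged
    if (fit$converged) {
      fit_a <- fit$a
      fit_b <- fit$b
      fit_c <- fit$c
      fit_d <- fit$d
      fit_rms <- fit$rms
      pb <- phase_boundaries(fit)
      ic <- pb$Ic
      id <- pb$Id
      clamped <- pb$clamped
      onset <- ic - birth
      duration <- pb$duration
      termination <- id
    }
  }

  out <- data.frame(
    pair_id = pair$pair_id,
    genotype = pair$genotype,
    n_frames = nrow(ser),
    starting_angle_deg = sf$starting_angle_deg,
    final_angle_deg = sf$final_angle_deg,
    final_angle_0180_deg = normalize_angle_0_180(sf$final_angle_deg),
    final_turn_deg = tail(ser$turn_deg, 1),
    max_turn_deg = max(ser$turn_deg),
    overshoot_deg = overshoot(ser),
    wobbling_deg = wobbling(ser),
    noise = nz$noise,
    noise_excluded = nz$excluded,
    handedness = hand$handedness,
    inverting = inv,
    fit_a_min = fit_a,
    fit_b_per_min = fit_b,
    fit_c_deg = fit_c,
    fit_d_deg = fit_d,
    fit_rms_deg = fit_rms,
    fit_failed = fit_failed,
    Ic_min = ic,
    Id_min = id,
    boundaries_clamped = clamped,
    onset_min = onset,
    duration_min = duration,
    termination_min = termination,
    stringsAsFactors = FALSE
  )
  class(out) <- c("rotation_metrics", "data.frame")
  out
}

#' Rotation metrics for a cohort of pairs
#'
#' @param tracks a `track_table`.
#' @param pairs data.frame with columns `pair_id`, `track_a`, `track_b` and
#'   optionally `genotype` (default `"wild-type"`).
#' @param config a [run_config()].
#' @return data.frame with one [rotation_metrics()] row per pair.
#' @export
analyze_pairs <- function(tracks, pairs, config) {
  stopifnot(all(c("pair_id", "track_a", "track_b") %in% names(pairs)))
  if (!"genotype" %in% names(pairs)) pairs$genotype <- "wild-type"
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- cell_pair(tracks, pairs$track_a[i], pairs$track_b[i],
      pair_id = pairs$pair_id[i], genotype = pairs$genotype[i]
    )
    rotation_metrics(p, config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
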