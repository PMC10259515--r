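#' Build a sibling-pair record from two tracks
#'
#' Extracts two tracks from a `track_table` and pairs them on their common
#' frame grid. Both tracks must be defined on identical frames (use
#' `align = TRUE` to intersect the grids first).
#'
#' @param tracks a `track_table` (see [read_track_table()]).
#' @param id_a,id_b track identifiers of the two sibling cells.
#' @param pair_id label for the pair.
#' @param genotype one of `"wild-type"`, `"emx2-/-"`, `"notch1a-/-"`,
#'   `"synthetic"`.
#' @param birth_frame frame of the progenitor division; defaults to the first
#'   common frame.
#' @param align intersect the two frame grids instead of requiring identity.
#' @return object of class `cell_pair`: list with `frames`, `times_min`,
#'   `xy_a`, `xy_b` (n x 2 matrices), `pair_id`, `genotype`, `birth_frame`,
#'   `centered` flag.
#' @export
cell_pair <- function(tracks, id_a, id_b, pair_id = paste(id_a, id_b, sep = "+"),
                      genotype = c("wild-type", "emx2-/-", "notch1a-/-", "synthetic"),
                      birth_frame = NULL, align = FALSE) {
  genotype <- match.arg(genotype)
  ta <- tracks[tracks$track_id == id_a, , drop = FALSE]
  tb <- tracks[tracks$track_id == id_b, , drop = FALSE]
  if (nrow(ta) == 0 || nrow(tb) == 0) {
    stop("track not found: ", if (nrow(ta) == 0) id_a else id_b, call. = FALSE)
  }
  if (align) {
    common <- intersect(ta$frame, tb$frame)
    ta <- ta[ta$frame %in% common, , drop = FALSE]
    tb <- tb[tb$frame %in% common, , drop = FALSE]
  }
  if (!identical(ta$frame, tb$frame)) {
    stop("the two tracks are not defined on identical frames", call. = FALSE)
  }
  if (nrow(ta) < 2) stop("a pair needs at least 2 frames", call. = FALSE)
  structure(
    list(
      pair_id = pair_id,
      genotype = genotype,
      frames = ta$frame,
      times_min = ta$time_min,
      xy_a = cbind(x = ta$x_um, y = ta$y_um),
      xy_b = cbind(x = tb$x_um, y = tb$y_um),
      birth_frame = if (is.null(birth_frame)) ta$frame[1] else birth_frame,
      centered = FALSE
    ),
    class = "cell_pair"
  )
}

#' @export
print.cell_pair <- function(x, ...) {
  cat(sprintf(
    "cell_pair '%s' (%s): %d frames, %.1f-%.1f min%s\n",
    x$pair_id, x$genotype, length(x$frames),
    min(x$times_min), max(x$times_min),
    if (x$centered) ", centered" else ""
  ))
  invisible(x)
}

#' Center a pair on its per-frame geometric midpoint
#'
#' At every frame the mean of the two positions is translated to the origin,
#' removing any common drift of the pair.
#'
#' @param pair a [cell_pair()].
#' @return the centered `cell_pair`.
#' @export
center_pair <- function(pair) {
  stopifnot(inherits(pair, "cell_pair"))
  mid <- (pair$xy_a + pair$xy_b) / 2
  pair$xy_a <- pair$xy_a - mid
  pair$xy_b <- pair$xy_b - mid
  pair$centered <- TRUE
  pair
}

#' Positional angle of the inter-cell axis
#'
#' Angle of the vector from cell A to cell B against the +x (anteroposterior)
#' axis, counter-clockwise positive, in (-180, 180].
#'
#' @param pair a [cell_pair()] (centered or not; the angle is
#'   translation-invariant).
#' @param frame optional subset of frames; default all.
#' @return numeric vector of angles in degrees.
#' @export
positional_angle <- function(pair, frame = NULL) {
  stopifnot(inherits(pair, "cell_pair"))
  idx <- if (is.null(frame)) seq_along(pair$frames) else match(frame, pair$frames)
  if (anyNA(idx)) stop("frame not in pair grid", call. = FALSE)
  d <- pair$xy_b[idx, , drop = FALSE] - pair$xy_a[idx, , drop = FALSE]
  r <- sqrt(d[, 1]^2 + d[, 2]^2)
  if (any(r < 1e-12)) {
    stop(
      "undefined angle: coincident centroids at frame(s) ",
      paste(pair$frames[idx][r < 1e-12], collapse = ", "),
      call. = FALSE
    )
  }
  unname(atan2(d[, 2], d[, 1]) * 180 / pi)
}

#' Per-frame angle series of a rotating pair
#'
#' Computes the positional angle at every frame, the wrapped frame-to-frame
#' change (minimal representative in (-180, 180], counter-clockwise positive),
#' the cumulative signed angle, the turn (absolute cumulative angle) and the
#' arc length (sum of absolute changes).
#'
#' @param pair a [cell_pair()].
#' @return object of class `angle_series`: data.frame with columns `frame`,
#'   `time_min`, `alpha_deg`, `dalpha_deg` (NA at the first frame), `cum_deg`,
#'   `turn_deg`, `arc_deg`; attributes `pair_id`, `genotype`, `birth_time_min`.
#' @export
angle_series <- function(pair) {
  stopifnot(inherits(pair, "cell_pair"))
  alpha <- positional_angle(pair)
  dal <- wrap_angle_180(diff(alpha))
  cum <- c(0, cumsum(dal))
  arc <- c(0, cumsum(abs(dal)))
  out <- data.frame(
    frame = pair$frames,
    time_min = pair$times_min,
    alpha_deg = alpha,
    dalpha_deg = c(NA_real_, dal),
    cum_deg = cum,
    turn_deg = abs(cum),
    arc_deg = arc
  )
  attr(out, "pair_id") <- pair$pair_id
  attr(out, "genotype") <- pair$genotype
  attr(out, "birth_time_min") <- pair$times_min[match(pair$birth_frame, pair$frames)]
  class(out) <- c("angle_series", "data.frame")
  out
}
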