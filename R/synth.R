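#' Parameters for synthesizing a sibling-pair trajectory
#'
#' Defaults encode the study conditions: 200 s frame interval, observation up
#' to 500 min (150 frames), rotation onset near 100 min with a Phase-2
#' duration of 50 min (`4/b`), a net rotation of 170 degrees for inverting
#' pairs, and sub-critical 30-degree rocking for non-inverting pairs. Wobble
#' is injected in angle space as independent Gaussian noise per frame so that
#' angular-path statistics can be set analytically.
#'
#' @param inverting logical; inverting (logistic) or rocking (sinusoidal)
#'   pair.
#' @param a_min logistic midpoint time, minutes.
#' @param b_per_min logistic steepness, 1/min (> 0 for inverting pairs).
#' @param c_deg,d_deg low and high asymptotes of the cumulative angle,
#'   degrees.
#' @param wobble_sd_deg per-frame angular noise SD, degrees (>= 0).
#' @param rock_amplitude_deg,rock_period_min sinusoidal rocking amplitude
#'   (< 90 so the pair stays sub-critical) and period, for non-inverting
#'   pairs.
#' @param pair_radius_um distance of each cell from the pair centroid.
#' @param initial_angle_deg positional angle of the inter-cell axis at birth.
#' @param n_frames number of frames.
#' @param frame_interval_s acquisition interval, seconds.
#' @param drift_um_per_min length-2 drift velocity of the pair centroid.
#' @return list of class `pair_synthesis_params`.
#' @export
pair_synthesis_params <- function(inverting = TRUE,
                                  a_min = 100, b_per_min = 0.08,
                                  c_deg = 0, d_deg = 170,
                                  wobble_sd_deg = 5,
                                  rock_amplitude_deg = 30,
                                  rock_period_min = 100,
                                  pair_radius_um = 4,
                                  initial_angle_deg = 0,
                                  n_frames = 150,
                                  frame_interval_s = 200,
                                  drift_um_per_min = c(0, 0)) {
  stopifnot(
    wobble_sd_deg >= 0, pair_radius_um > 0, n_frames >= 2,
    frame_interval_s > 0, length(drift_um_per_min) == 2
  )
  if (inverting && b_per_min <= 0) {
    stop("b_per_min must be > 0 for inverting pairs", call. = FALSE)
  }
  if (!inverting && !(rock_amplitude_deg >= 0 && rock_amplitude_deg < 90)) {
    stop("rock_amplitude_deg must be in [0, 90)", call. = FALSE)
  }
  structure(
    list(
      inverting = inverting, a_min = a_min, b_per_min = b_per_min,
      c_deg = c_deg, d_deg = d_deg, wobble_sd_deg = wobble_sd_deg,
      rock_amplitude_deg = rock_amplitude_deg,
      rock_period_min = rock_period_min,
      pair_radius_um = pair_radius_um,
      initial_angle_deg = initial_angle_deg,
      n_frames = n_frames, frame_interval_s = frame_interval_s,
      drift_um_per_min = drift_um_per_min
    ),
    class = "pair_synthesis_params"
  )
}

synth_axis_angle <- function(params, times, wobble) {
  base <- if (params$inverting) {
    params$initial_angle_deg + params$c_deg +
      (params$d_deg - params$c_deg) /
        (1 + exp(-params$b_per_min * (times - params$a_min)))
  } else {
    params$initial_angle_deg +
      params$rock_amplitude_deg * sin(2 * pi * times / params$rock_period_min)
  }
  base + wobble
}

#' Generate a mirror-symmetric sibling-pair track table
#'
#' Two tracks (`"cell_a"`, `"cell_b"`) mirror-symmetric about a (possibly
#' drifting) pair centroid at radius `pair_radius_um`. For inverting pairs
#' the noise-free axis angle follows the four-parameter logistic
#' `c + (d - c)/(1 + exp(-b (t - a)))` added to the initial angle; for
#' non-inverting pairs it oscillates sinusoidally about the initial angle.
#' Per-frame Gaussian wobble is added in angle space. Pure function of
#' (params, seed).
#'
#' @param params a [pair_synthesis_params()].
#' @param seed integer seed.
#' @return a `track_table` with two tracks.
#' @export
generate_pair_tracks <- function(params, seed) {
  stopifnot(inherits(params, "pair_synthesis_params"))
  withr::with_seed(seed, {
    n <- params$n_frames
    dt <- params$frame_interval_s / 60
    times <- (seq_len(n) - 1) * dt
    wob <- if (params$wobble_sd_deg > 0) {
      rnorm(n, 0, params$wobble_sd_deg)
    } else {
      numeric(n)
    }
    alpha <- synth_axis_angle(params, times, wob)
    cx <- params$drift_um_per_min[1] * times
    cy <- params$drift_um_per_min[2] * times
    u <- cbind(cos(alpha * pi / 180), sin(alpha * pi / 180))
    r <- params$pair_radius_um
    tab <- rbind(
      data.frame(
        track_id = "cell_a", frame = seq_len(n) - 1L, time_min = times,
        x_um = cx - r * u[, 1], y_um = cy - r * u[, 2]
      ),
      data.frame(
        track_id = "cell_b", frame = seq_len(n) - 1L, time_min = times,
        x_um = cx + r * u[, 1], y_um = cy + r * u[, 2]
      )
    )
    class(tab) <- c("track_table", "data.frame")
    tab
  })
}

#' Generate phase-correlated morphology and junction fixtures
#'
#' Emits Tissue-Analyzer-style cell and bond tables for one synthetic sibling
#' pair: constant areas, a shared-junction length and pair circularity that
#' rise to a peak inside Phase 2 (between the tangent-intersection times
#' implied by the pair's logistic parameters) and fall in Phase 3, an
#' inter-centroid distance that dips during Phase 2, and a per-frame interface
#' polyline of a selectable shape class. Perimeters are derived from the
#' targeted circularity, so recomputing `4 pi A / P^2` on the emitted rows
#' reproduces the requested series exactly.
#'
#' @param pair_params a [pair_synthesis_params()] (inverting).
#' @param seed integer seed (wobble of the underlying tracks).
#' @param area_um2 per-cell area (constant).
#' @param circ_base,circ_peak baseline and Phase-2 peak pair circularity.
#' @param junction_base_um,junction_peak_um baseline and peak shared-junction
#'   lengths.
#' @param distance_dip_frac fractional dip of the inter-cell distance at the
#'   Phase-2 peak.
#' @param shape_class interface shape emitted (`"I"`, `"C"`, `"S"`, `"Z"`).
#' @param drop_bond_frames frames (0-based) at which no bond row is emitted,
#'   to exercise missing-junction handling.
#' @return a `cell_bond_tables`.
#' @export
generate_morph_series <- function(pair_params, seed,
                                  area_um2 = 30,
                                  circ_base = 0.55, circ_peak = 0.9,
                                  junction_base_um = 1, junction_peak_um = 4,
                                  distance_dip_frac = 0.2,
                                  shape_class = c("I", "C", "S", "Z"),
                                  drop_bond_frames = integer(0)) {
  stopifnot(inherits(pair_params, "pair_synthesis_params"), pair_params$inverting)
  shape_class <- match.arg(shape_class)
  n <- pair_params$n_frames
  dt <- pair_params$frame_interval_s / 60
  times <- (seq_len(n) - 1) * dt
  ic <- pair_params$a_min - 2 / pair_params$b_per_min
  id <- pair_params$a_min + 2 / pair_params$b_per_min
  bump <- exp(-(times - pair_params$a_min)^2 / (2 * ((id - ic) / 4)^2))

  circ <- circ_base + (circ_peak - circ_base) * bump
  shared <- junction_base_um + (junction_peak_um - junction_base_um) * bump
  radius <- pair_params$pair_radius_um * (1 - distance_dip_frac * bump)

  dp <- pair_params
  dp$pair_radius_um <- 1 # direction only; radii modulated below
  tracks <- generate_pair_tracks(dp, seed)
  a <- tracks[tracks$track_id == "cell_a", ]
  b <- tracks[tracks$track_id == "cell_b", ]
  ux <- (b$x_um - a$x_um) / 2
  uy <- (b$y_um - a$y_um) / 2
  ax <- a$x_um + ux - radius * ux
  ay <- a$y_um + uy - radius * uy
  bx <- a$x_um + ux + radius * ux
  by <- a$y_um + uy + radius * uy

  p_eff <- sqrt(4 * pi * 2 * area_um2 / circ)
  perim <- (p_eff + 2 * shared) / 2

  cells <- data.frame(
    cell_id = rep(c("cell_a", "cell_b"), each = n),
    frame = rep(seq_len(n) - 1L, 2),
    cx_um = c(ax, bx), cy_um = c(ay, by),
    area_um2 = area_um2,
    perimeter_um = rep(perim, 2),
    stringsAsFactors = FALSE
  )

  keep <- !(seq_len(n) - 1L) %in% drop_bond_frames
  mids <- cbind((ax + bx) / 2, (ay + by) / 2)
  # right-handed local frame: template x along the interface (perpendicular
  # to the inter-cell axis), template y 90 deg counter-clockwise from it, so
  # the emitted chirality matches the template's
  e1 <- cbind(-uy, ux) / sqrt(ux^2 + uy^2)
  e2 <- cbind(-e1[, 2], e1[, 1])
  polys <- lapply(which(keep), function(i) {
    tpl <- template_interface(shape_class, L = shared[i])
    cbind(
      x = mids[i, 1] + tpl[, 1] * e1[i, 1] + tpl[, 2] * e2[i, 1],
      y = mids[i, 2] + tpl[, 1] * e1[i, 2] + tpl[, 2] * e2[i, 2]
    )
  })
  bonds <- data.frame(
    frame = (seq_len(n) - 1L)[keep],
    cell_id_a = "cell_a", cell_id_b = "cell_b",
    length_um = shared[keep],
    stringsAsFactors = FALSE
  )
  bonds$polyline <- polys
  structure(list(cells = cells, bonds = bonds), class = "cell_bond_tables")
}

template_interface <- function(class, L, n_pts = 33, amp_frac = 0.25) {
  x <- seq(-L / 2, L / 2, length.out = n_pts)
  h <- amp_frac * L
  y <- switch(class,
    I = rep(0, n_pts),
    C = h * (1 - (2 * x / L)^2),
    S = h * sin(2 * pi * x / L),
    Z = -h * sin(2 * pi * x / L)
  )
  cbind(x, y)
}

#' Generate a synthetic neighbor-count series
#'
#' Two integer neighbor-count sequences around a base count. With `bias = 0`
#' neighbor exchange is symmetric: both counts share a common fluctuation
#' plus a telescoping exchange term, so the cumulative difference `D(T)`
#' stays bounded with mean about zero. With a nonzero `bias` one cell has
#' exactly `bias` more neighbors at every frame (a "popular" cell), so
#' `D(T) = bias * T` exactly.
#'
#' @param n_frames number of frames.
#' @param bias integer per-frame neighbor surplus of cell A (may be
#'   negative).
#' @param p_exchange per-frame probability of a neighbor exchange event.
#' @param seed integer seed.
#' @param base_neighbors baseline neighbor count (default 6, a typical
#'   epithelial coordination number).
#' @return a `neighbor_series`.
#' @export
generate_neighbor_series <- function(n_frames, bias = 0, p_exchange = 0.3,
                                     seed = 1, base_neighbors = 6) {
  stopifnot(n_frames >= 1, base_neighbors + bias >= 0)
  withr::with_seed(seed, {
    shared <- cumsum(sample(c(-1L, 0L, 1L), n_frames,
      replace = TRUE,
      prob = c(p_exchange / 2, 1 - p_exchange, p_exchange / 2)
    ))
    shared <- pmax(pmin(shared, 2L), -2L) # bounded common fluctuation
    if (bias == 0) {
      z <- as.integer(runif(n_frames) < p_exchange) # telescoping exchange
      n_a <- base_neighbors + shared + c(z[-1], z[n_frames])
      m_b <- base_neighbors + shared + z
    } else {
      n_a <- base_neighbors + shared + as.integer(bias)
      m_b <- base_neighbors + shared
    }
    out <- data.frame(frame = seq_len(n_frames) - 1L, n_a = n_a, m_b = m_b)
    class(out) <- c("neighbor_series", "data.frame")
    out
  })
}

#' Generate a synthetic epithelium track table
#'
#' `n_cells` independent stationary tracks with per-frame Gaussian positional
#' jitter, uniformly placed in a disc-shaped arena, optionally with one
#' embedded mirror-rotating sibling pair (tracks `"hc_a"`, `"hc_b"`).
#' Emulates particle tracking of a neuromast whose center is kept spatially
#' fixed.
#'
#' @param n_cells number of background cells (>= 1).
#' @param seed integer seed.
#' @param arena_radius_um placement disc radius.
#' @param jitter_sd_um per-frame positional jitter SD.
#' @param n_frames frames.
#' @param frame_interval_s acquisition interval, seconds.
#' @param embedded_pair optional [pair_synthesis_params()] for an embedded
#'   rotating pair.
#' @return a `track_table`.
#' @export
generate_epithelium <- function(n_cells = 10, seed = 1,
                                arena_radius_um = 15, jitter_sd_um = 0.15,
                                n_frames = 100, frame_interval_s = 200,
                                embedded_pair = NULL) {
  stopifnot(n_cells >= 1)
  bg <- withr::with_seed(seed, {
    dt <- frame_interval_s / 60
    times <- (seq_len(n_frames) - 1) * dt
    rows <- lapply(seq_len(n_cells), function(i) {
      rr <- arena_radius_um * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      data.frame(
        track_id = sprintf("cell_%02d", i),
        frame = seq_len(n_frames) - 1L,
        time_min = times,
        x_um = rr * cos(th) + rnorm(n_frames, 0, jitter_sd_um),
        y_um = rr * sin(th) + rnorm(n_frames, 0, jitter_sd_um)
      )
    })
    do.call(rbind, rows)
  })
  if (!is.null(embedded_pair)) {
    hp <- embedded_pair
    hp$n_frames <- n_frames
    hp$frame_interval_s <- frame_interval_s
    pp <- generate_pair_tracks(hp, seed + 1L)
    pp$track_id <- ifelse(pp$track_id == "cell_a", "hc_a", "hc_b")
    bg <- rbind(bg, pp)
  }
  class(bg) <- c("track_table", "data.frame")
  bg
}
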