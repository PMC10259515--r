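# Shared fixtures, built in code at test time.

default_config <- function(...) run_config(unit_scale = 1, ...)

# track table from explicit per-track coordinate lists
make_tracks <- function(..., frame_interval_s = 200) {
  dt <- frame_interval_s / 60
  tracks <- list(...)
  rows <- lapply(names(tracks), function(id) {
    xy <- tracks[[id]]
    n <- nrow(xy)
    data.frame(
      track_id = id, frame = seq_len(n) - 1L,
      time_min = (seq_len(n) - 1) * dt,
      x_um = xy[, 1], y_um = xy[, 2]
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("track_table", "data.frame")
  out
}

# pair whose axis angle follows a given per-frame angle vector (degrees)
pair_from_angles <- function(alpha_deg, radius = 2, genotype = "synthetic") {
  a <- alpha_deg * pi / 180
  tr <- make_tracks(
    a = cbind(-radius * cos(a), -radius * sin(a)),
    b = cbind(radius * cos(a), radius * sin(a))
  )
  cell_pair(tr, "a", "b", pair_id = "p", genotype = genotype)
}

# smooth random interface polyline from low-order Fourier modes
random_polyline <- function(n_pts = 41, L = 4, n_modes = 3) {
  x <- seq(-L / 2, L / 2, length.out = n_pts)
  y <- rep(0, n_pts)
  for (k in seq_len(n_modes)) {
    y <- y + rnorm(1, 0, 0.3 * L / k) * sin(k * pi * (x / L + 0.5))
  }
  cbind(x = x, y = y)
}

# regular polygon approximation of a half-disc (flat side the diameter)
half_disc_polygon <- function(r = 1, n_arc = 200, upper = TRUE) {
  th <- seq(0, pi, length.out = n_arc + 1)
  if (!upper) th <- -th
  cbind(x = r * cos(th), y = r * sin(th))
}

polygon_area <- function(p) {
  x <- p[, 1]
  y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(p) {
  q <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(q)^2)))
}
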