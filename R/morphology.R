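#' Circularity of a cell pair taken as a unit
#'
#' Isoperimetric ratio `C = 4 pi A / P^2` with `A` the summed area of both
#' cells and `P` the summed perimeter minus twice the length of the shared
#' membrane segment (the homotypic junction is interior to the pair outline).
#' `C = 1` for a perfect disc. Defined only at frames where the siblings share
#' a bond; values slightly above 1 (possible with segmentation noise) are
#' clamped to 1 with a flag.
#'
#' @param area_1,area_2 cell areas, square micrometres.
#' @param perimeter_1,perimeter_2 cell perimeters, micrometres.
#' @param shared_length length of the shared membrane segment, micrometres
#'   (0 or NA means no bond: circularity undefined).
#' @return list with `circularity` (in `[0, 1]` or NA) and `clamped` flag.
#' @export
pair_circularity <- function(area_1, area_2, perimeter_1, perimeter_2,
                             shared_length) {
  if (is.na(shared_length) || shared_length <= 0) {
    return(list(circularity = NA_real_, clamped = FALSE))
  }
  if (shared_length > min(perimeter_1, perimeter_2)) {
    stop("shared segment longer than a cell perimeter", call. = FALSE)
  }
  a <- area_1 + area_2
  p <- perimeter_1 + perimeter_2 - 2 * shared_length
  cc <- 4 * pi * a / p^2
  clamped <- cc > 1
  list(circularity = min(cc, 1), clamped = clamped)
}

#' Per-frame morphology series of a sibling pair
#'
#' Aligns the segmentation-derived quantities of the two siblings on the
#' frame grid: areas, perimeters, shared-junction length (0 at frames without
#' a bond), pair circularity (NA without a bond), inter-centroid distance and
#' the interface polyline when exported.
#'
#' @param tables a `cell_bond_tables` (see [read_cell_bond_tables()]).
#' @param id_a,id_b sibling cell ids.
#' @return data.frame of class `morph_series` with columns `frame`, `area_1`,
#'   `area_2`, `perimeter_1`, `perimeter_2`, `shared_length_um`,
#'   `distance_um`, `circularity`, `circularity_clamped`, plus a `polyline`
#'   list-column.
#' @export
junction_and_distance_series <- function(tables, id_a, id_b) {
  stopifnot(inherits(tables, "cell_bond_tables"))
  ca <- tables$cells[tables$cells$cell_id == id_a, , drop = FALSE]
  cb <- tables$cells[tables$cells$cell_id == id_b, , drop = FALSE]
  frames <- intersect(ca$frame, cb$frame)
  if (length(frames) == 0) stop("cells share no frames", call. = FALSE)
  frames <- sort(frames)
  ia <- match(frames, ca$frame)
  ib <- match(frames, cb$frame)
  b <- tables$bonds
  sib <- b[(b$cell_id_a == id_a & b$cell_id_b == id_b) |
    (b$cell_id_a == id_b & b$cell_id_b == id_a), , drop = FALSE]
  jb <- match(frames, sib$frame)
  shared <- ifelse(is.na(jb), 0, sib$length_um[jb])
  poly <- lapply(jb, function(j) if (is.na(j)) NULL else sib$polyline[[j]])
  dist <- sqrt((ca$cx_um[ia] - cb$cx_um[ib])^2 + (ca$cy_um[ia] - cb$cy_um[ib])^2)
  circ <- mapply(
    function(a1, a2, p1, p2, sl) {
      unlist(pair_circularity(a1, a2, p1, p2, sl))
    },
    ca$area_um2[ia], cb$area_um2[ib], ca$perimeter_um[ia], cb$perimeter_um[ib],
    shared
  )
  out <- data.frame(
    frame = frames,
    area_1 = ca$area_um2[ia], area_2 = cb$area_um2[ib],
    perimeter_1 = ca$perimeter_um[ia], perimeter_2 = cb$perimeter_um[ib],
    shared_length_um = shared,
    distance_um = dist,
    circularity = as.numeric(circ["circularity", ]),
    circularity_clamped = as.logical(circ["clamped", ])
  )
  out$polyline <- poly
  class(out) <- c("morph_series", "data.frame")
  out
}

#' Canonicalize an interface polyline
#'
#' Rigidly rotates and translates a polyline so that its two endpoints lie on
#' the x axis at `(-L/2, 0)` and `(+L/2, 0)`, where `L` is the endpoint
#' separation. Only rotation and translation are applied (no reflection), and
#' the traversal order is preserved, so chirality is conserved.
#'
#' @param polyline n x 2 numeric matrix of ordered (x, y) points, n >= 2.
#' @return canonicalized n x 2 matrix with attribute `L` (endpoint
#'   separation).
#' @export
canonicalize_interface <- function(polyline) {
  p <- as.matrix(polyline)
  if (nrow(p) < 2) stop("polyline needs at least 2 points", call. = FALSE)
  p0 <- p[1, ]
  p1 <- p[nrow(p), ]
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len < 1e-12) stop("coincident polyline endpoints", call. = FALSE)
  theta <- atan2(v[2], v[1])
  rot <- matrix(c(cos(-theta), sin(-theta), -sin(-theta), cos(-theta)), 2, 2)
  q <- sweep(p, 2, (p0 + p1) / 2) %*% t(rot)
  colnames(q) <- c("x", "y")
  attr(q, "L") <- len
  q
}

resample_polyline <- function(p, n = 64) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < 1e-12) stop("degenerate polyline", call. = FALSE)
  u <- seq(0, total, length.out = n)
  cbind(
    x = approx(s, p[, 1], xout = u, ties = "ordered")$y,
    y = approx(s, p[, 2], xout = u, ties = "ordered")$y
  )
}

#' Classify the chirality class of a sibling interface
#'
#' Classifies a canonicalized interface polyline as straight (`I`), curved
#' (`C`), or one of the two chiral sigmoids (`S`, `Z`; `Z` denotes the
#' mirrored S). The polyline is resampled to `n_points` arc-length-uniform
#' points. The x-asymmetry score is the mean absolute difference between the
#' transverse offsets at arc positions mirrored about the midpoint,
#' `mean(|y(u) - y(1-u)|) / 2`, and the y-asymmetry score the mean absolute
#' offset `mean(|y|)`, both normalized by the endpoint separation. Precedence
#' follows the study's rule: a sigmoid call (x-asymmetry above `tau_s`) wins
#' over a curvature call (y-asymmetry above `tau_c`); a curve with no notable
#' asymmetry on either axis is straight. The sigmoid sign is the side of the
#' leading (first-traversed) lobe: leading lobe below the axis gives `S`,
#' above gives `Z`, so mirroring swaps the two chiral classes and fixes `I`
#' and `C`.
#'
#' @param polyline n x 2 matrix (canonicalized internally).
#' @param tau_s,tau_c classification thresholds as fractions of the endpoint
#'   separation (defaults 0.05).
#' @param n_points resampling density (default 64).
#' @return list with `class` (factor in I/C/S/Z), `x_asymmetry`,
#'   `y_asymmetry`.
#' @export
classify_interface_shape <- function(polyline, tau_s = 0.05, tau_c = 0.05,
                                     n_points = 64) {
  q <- canonicalize_interface(polyline)
  L <- attr(q, "L")
  r <- resample_polyline(q, n_points)
  y <- r[, 2]
  n <- length(y)
  x_asym <- mean(abs(y - rev(y))) / (2 * L)
  y_asym <- mean(abs(y)) / L
  half <- seq_len(floor(n / 2))
  lead <- mean(y[half]) - mean(y[n + 1 - half])
  cls <- if (x_asym > tau_s) {
    if (lead < 0) "S" else "Z"
  } else if (y_asym > tau_c) {
    "C"
  } else {
    "I"
  }
  list(
    class = factor(cls, levels = c("I", "C", "S", "Z")),
    x_asymmetry = x_asym,
    y_asymmetry = y_asym
  )
}

#' Interface shape-class census over pairs and frames
#'
#' Tabulates the interface shape classes of all frames with an exported
#' interface polyline, as counts and percentages.
#'
#' @param morph a `morph_series` (or list of them).
#' @param ... passed to [classify_interface_shape()].
#' @return data.frame with columns `class`, `count`, `percent`.
#' @export
interface_shape_census <- function(morph, ...) {
  if (inherits(morph, "morph_series")) morph <- list(morph)
  cls <- unlist(lapply(morph, function(m) {
    keep <- !vapply(m$polyline, is.null, logical(1))
    vapply(
      m$polyline[keep],
      function(p) as.character(classify_interface_shape(p, ...)$class),
      character(1)
    )
  }))
  tab <- table(factor(cls, levels = c("I", "C", "S", "Z")))
  data.frame(
    class = names(tab),
    count = as.integer(tab),
    percent = if (sum(tab) > 0) 100 * as.integer(tab) / sum(tab) else rep(NA_real_, 4)
  )
}
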