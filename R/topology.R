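#' Per-frame cell-neighbor network
#'
#' Builds one undirected graph per frame from the bond table: cells are nodes
#' and two cells are adjacent iff a bond row links them at that frame. Frames
#' with cells but no bonds yield edgeless graphs.
#'
#' @param tables a `cell_bond_tables`.
#' @return named list of `igraph` graphs, one per frame (names are frame
#'   indices), class `dynamic_network`.
#' @export
build_dynamic_network <- function(tables) {
  stopifnot(inherits(tables, "cell_bond_tables"))
  frames <- sort(unique(tables$cells$frame))
  graphs <- lapply(frames, function(f) {
    verts <- unique(tables$cells$cell_id[tables$cells$frame == f])
    eb <- tables$bonds[tables$bonds$frame == f, c("cell_id_a", "cell_id_b"),
      drop = FALSE
    ]
    igraph::graph_from_data_frame(eb,
      directed = FALSE,
      vertices = data.frame(name = verts)
    )
  })
  names(graphs) <- frames
  class(graphs) <- c("dynamic_network", class(graphs))
  graphs
}

#' Neighbor-count series of a sibling pair
#'
#' Per-frame neighbor counts of the two siblings in the dynamic network. By
#' the study's convention cell A is the sibling that finishes on the anterior
#' side (retrospectively the Notch-off/Emx2-positive cell) and cell B the
#' posterior finisher; use [label_siblings()] to order the ids from final
#' positions. The sibling-sibling bond is counted in both cells' neighbor
#' sets; because it contributes equally to both counts it cancels from every
#' difference `N_t - M_t`.
#'
#' @param network a `dynamic_network` (see [build_dynamic_network()]).
#' @param id_a,id_b cell ids of the anterior- and posterior-finishing sibling.
#' @return data.frame of class `neighbor_series` with columns `frame`, `n_a`,
#'   `m_b`.
#' @export
neighbor_series <- function(network, id_a, id_b) {
  frames <- as.integer(names(network))
  count <- function(g, id) {
    if (!id %in% igraph::V(g)$name) {
      return(NA_integer_)
    }
    length(igraph::neighbors(g, id))
  }
  out <- data.frame(
    frame = frames,
    n_a = vapply(network, count, integer(1), id = id_a),
    m_b = vapply(network, count, integer(1), id = id_b)
  )
  out <- out[!is.na(out$n_a) & !is.na(out$m_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("neighbor_series", "data.frame")
  out
}

#' Order two sibling ids by final anteroposterior position
#'
#' The anterior-finishing sibling (lower x over the last `k` frames, x
#' increasing posterior) is returned first; this is the retrospective
#' Notch-off/Emx2-positive label used throughout the topology analysis.
#'
#' @param pair a [cell_pair()].
#' @param id_a,id_b the ids corresponding to the pair's tracks A and B.
#' @param k frames averaged at the end (default 10).
#' @return character vector `c(anterior_id, posterior_id)`.
#' @export
label_siblings <- function(pair, id_a, id_b, k = 10) {
  stopifnot(inherits(pair, "cell_pair"))
  n <- nrow(pair$xy_a)
  kk <- min(k, n)
  xa <- mean(pair$xy_a[(n - kk + 1):n, 1])
  xb <- mean(pair$xy_b[(n - kk + 1):n, 1])
  if (xa <= xb) c(id_a, id_b) else c(id_b, id_a)
}

#' Cumulative difference in neighbor numbers
#'
#' `D(T) = sum_{t=1..T} (N_t - M_t)`: stays near zero when neighbor exchange
#' is symmetric between the siblings, and diverges linearly when one cell (the
#' "popular" one) consistently has more neighbors.
#'
#' @param series a [neighbor_series()] (or data.frame with `n_a`, `m_b`).
#' @param T frame count up to which to accumulate; default the full series.
#' @param cumulative return the whole `D(1..T)` path instead of the endpoint.
#' @return `D(T)` (integer) or, with `cumulative = TRUE`, an integer vector.
#' @export
cumulative_neighbor_difference <- function(series, T = nrow(series),
                                           cumulative = FALSE) {
  stopifnot(all(c("n_a", "m_b") %in% names(series)))
  if (T < 1 || T > nrow(series)) {
    stop("T out of range 1..", nrow(series), call. = FALSE)
  }
  d <- cumsum(series$n_a - series$m_b)
  if (cumulative) d[seq_len(T)] else d[T]
}

#' Detect a persistently "popular" sibling
#'
#' A sibling is popular when it consistently has more neighbors than the
#' other, which makes `D(T)` diverge. The decision rule: a two-sided sign
#' test on the nonzero per-frame differences at level `alpha`; when symmetry
#' is rejected, the popular cell is read from the sign of the least-squares
#' slope of `D(T)` against `T`.
#'
#' @param series a [neighbor_series()] with at least 20 frames.
#' @param alpha sign-test level (default 0.05).
#' @return list with `popular` (`"A"`, `"B"` or `"none"`), `slope`
#'   (neighbors/frame) and `p_sign`.
#' @export
popular_cell <- function(series, alpha = 0.05) {
  stopifnot(nrow(series) >= 20)
  diffs <- series$n_a - series$m_b
  d <- cumsum(diffs)
  tt <- seq_along(d)
  slope <- unname(coef(lm(d ~ tt))[2])
  nz <- diffs[diffs != 0]
  p_sign <- if (length(nz) == 0) 1 else binom.test(sum(nz > 0), length(nz))$p.value
  popular <- if (p_sign < alpha) {
    if (slope > 0) "A" else "B"
  } else {
    "none"
  }
  list(popular = popular, slope = slope, p_sign = p_sign)
}

#' LOESS smoothing of cumulative neighbor-difference trajectories
#'
#' Locally weighted regression of `|D(T)|` (or signed `D(T)`) against frame,
#' per group (inverting vs non-inverting, typically), evaluated on the pooled
#' frame grid.
#'
#' @param trajectories data.frame with columns `group`, `frame`, `D`.
#' @param span loess span (default 0.75).
#' @param absolute smooth `|D|` (default) or signed `D`.
#' @param degree local polynomial degree (default 2).
#' @return data.frame with columns `group`, `frame`, `smoothed`.
#' @export
smooth_difference <- function(trajectories, span = 0.75, absolute = TRUE,
                              degree = 2) {
  stopifnot(all(c("group", "frame", "D") %in% names(trajectories)))
  out <- lapply(split(trajectories, trajectories$group), function(d) {
    y <- if (absolute) abs(d$D) else d$D
    fit <- loess(y ~ frame,
      data = data.frame(frame = d$frame, y = y),
      span = span, degree = degree, surface = "direct"
    )
    grid <- sort(unique(d$frame))
    data.frame(
      group = d$group[1], frame = grid,
      smoothed = predict(fit, newdata = data.frame(frame = grid))
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
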