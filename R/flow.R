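#' Anteroposterior displacement series of a track
#'
#' Frame-to-frame displacement along the A-P (x) axis, optionally after
#' subtracting the displacement of a reference track (e.g. the organ center),
#' which removes common drift. Movement, not position, is analyzed because
#' the position series of confined cells are trivially autocorrelated.
#'
#' @param track data.frame with columns `frame`, `x_um` (a single track).
#' @param reference optional reference track on the same frame grid.
#' @return data.frame with columns `frame` (the later frame of each step) and
#'   `dx_um`.
#' @export
ap_displacement_series <- function(track, reference = NULL) {
  stopifnot(all(c("frame", "x_um") %in% names(track)), nrow(track) >= 2)
  dx <- diff(track$x_um)
  if (!is.null(reference)) {
    if (!identical(track$frame, reference$frame)) {
      stop("reference track on a different frame grid", call. = FALSE)
    }
    dx <- dx - diff(reference$x_um)
  }
  data.frame(frame = track$frame[-1], dx_um = dx)
}

#' Movement correlation between cell classes of the epithelium
#'
#' Pearson correlation of the A-P displacement series for every unordered
#' pair of tracks, classified by membership of the rotating hair-cell pair:
#' `HC-HC` (the two rotating cells), `HC-other`, and `other-other`. Pairs
#' with fewer than `min_frames` common steps or a zero-variance displacement
#' series are skipped with a reason.
#'
#' @param tracks a `track_table`.
#' @param pair_ids character vector of the two rotating-cell track ids.
#' @param reference optional reference track (data.frame `frame`, `x_um`)
#'   subtracted from every displacement series.
#' @param min_frames minimal common steps (default 3).
#' @return data.frame of class `correlation_report`: columns `id_a`, `id_b`,
#'   `class`, `r`, `n`, `skipped`, `reason`.
#' @export
correlate_classes <- function(tracks, pair_ids, reference = NULL,
                              min_frames = 3) {
  ids <- unique(tracks$track_id)
  stopifnot(length(ids) >= 2)
  series <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    ref <- if (is.null(reference)) {
      NULL
    } else {
      reference[reference$frame %in% tr$frame, , drop = FALSE]
    }
    ap_displacement_series(tr, ref)
  })
  names(series) <- ids
  combs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]
    b <- combs[2, k]
    cls <- if (a %in% pair_ids && b %in% pair_ids) {
      "HC-HC"
    } else if (a %in% pair_ids || b %in% pair_ids) {
      "HC-other"
    } else {
      "other-other"
    }
    sa <- series[[a]]
    sb <- series[[b]]
    common <- intersect(sa$frame, sb$frame)
    xa <- sa$dx_um[match(common, sa$frame)]
    xb <- sb$dx_um[match(common, sb$frame)]
    row <- data.frame(
      id_a = a, id_b = b, class = cls, r = NA_real_,
      n = length(common), skipped = FALSE, reason = NA_character_,
      stringsAsFactors = FALSE
    )
    if (length(common) < min_frames) {
      row$skipped <- TRUE
      row$reason <- "fewer common frames than min_frames"
    } else if (sd(xa) < 1e-12 || sd(xb) < 1e-12) {
      row$skipped <- TRUE
      row$reason <- "zero-variance displacement series"
    } else {
      row$r <- cor(xa, xb)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Summarize a correlation report by cell-pair class
#'
#' Both the pooled-pair summary and a per-class median are reported, since
#' box plots of movement correlations can be read either way.
#'
#' @param report a `correlation_report`.
#' @return data.frame with columns `class`, `n_pairs`, `mean_r`, `median_r`.
#' @export
summarize_correlations <- function(report) {
  keep <- report[!report$skipped, , drop = FALSE]
  out <- do.call(rbind, lapply(split(keep, keep$class), function(d) {
    data.frame(
      class = d$class[1], n_pairs = nrow(d),
      mean_r = mean(d$r), median_r = median(d$r)
    )
  }))
  rownames(out) <- NULL
  out
}
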