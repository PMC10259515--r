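#' Read a tracked-centroid table
#'
#' Parses an MTrackJ-style CSV export with one row per tracked point. Required
#' columns: `track_id`, `frame`, and either `x`/`y` or `x_um`/`y_um`; an
#' optional `time_min` column overrides the time derived from
#' `frame * frame_interval`. Coordinates are multiplied by
#' `config$unit_scale` to micrometres. Rows beyond
#' `config$max_observation_min` are dropped; the number removed is kept in the
#' `n_dropped` attribute so that no in-range row is ever silently discarded.
#'
#' @param path CSV file path.
#' @param config a [run_config()].
#' @return a `track_table`: data.frame with columns `track_id` (character),
#'   `frame` (integer, 0-based), `time_min`, `x_um`, `y_um`.
#' @export
read_track_table <- function(path, config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  xcol <- if ("x_um" %in% names(raw)) "x_um" else "x"
  ycol <- if ("y_um" %in% names(raw)) "y_um" else "y"
  need <- c("track_id", "frame", xcol, ycol)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "track table format error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  dt_min <- config$frame_interval_s / 60
  tab <- data.frame(
    track_id = as.character(raw$track_id),
    frame = as.integer(raw$frame),
    time_min = if ("time_min" %in% names(raw)) {
      as.numeric(raw$time_min)
    } else {
      as.integer(raw$frame) * dt_min
    },
    x_um = as.numeric(raw[[xcol]]) * config$unit_scale,
    y_um = as.numeric(raw[[ycol]]) * config$unit_scale,
    stringsAsFactors = FALSE
  )
  validate_track_table(tab, dt_min)
  keep <- tab$time_min <= config$max_observation_min
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("track_table", "data.frame")
  out
}

validate_track_table <- function(tab, dt_min) {
  if (any(tab$frame < 0)) stop("negative frame index", call. = FALSE)
  key <- paste(tab$track_id, tab$frame)
  if (anyDuplicated(key)) {
    stop(
      "track table validation error: duplicate (track_id, frame): ",
      paste(unique(key[duplicated(key)]), collapse = "; "),
      call. = FALSE
    )
  }
  by_track <- split(tab$frame, tab$track_id)
  bad <- names(by_track)[vapply(by_track, function(f) any(diff(f) <= 0), logical(1))]
  if (length(bad) > 0) {
    stop(
      "track table validation error: frames not strictly increasing in track(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(dt_min)) {
    mismatch <- abs(tab$time_min - tab$frame * dt_min) > dt_min / 2
    if (any(mismatch)) {
      stop(
        "track table validation error: time_min inconsistent with frame interval in ",
        sum(mismatch), " row(s)",
        call. = FALSE
      )
    }
  }
  invisible(tab)
}

#' Read segmentation-derived cell and bond tables
#'
#' Parses Tissue-Analyzer-style exports: a cell table (`cell_id`, `frame`,
#' `cx_um`, `cy_um`, `area_um2`, `perimeter_um`) and a bond table (`frame`,
#' `cell_id_a`, `cell_id_b`, `length_um`, optional `polyline` serialized as
#' `"x1 y1;x2 y2;..."`). Coordinates, lengths and areas are scaled to
#' micrometres by `config$unit_scale` (squared for areas). Every bond must
#' reference two cell rows present at its frame.
#'
#' @param cell_path,bond_path CSV file paths.
#' @param config a [run_config()].
#' @return object of class `cell_bond_tables`: list with data.frames `cells`
#'   and `bonds` (the latter carrying a `polyline` list-column of n x 2
#'   matrices when present).
#' @export
read_cell_bond_tables <- function(cell_path, bond_path, config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(cell_path, bond_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  s <- config$unit_scale
  cells_raw <- read.csv(cell_path, stringsAsFactors = FALSE)
  need_c <- c("cell_id", "frame", "cx", "cy", "area", "perimeter")
  alt_c <- c("cell_id", "frame", "cx_um", "cy_um", "area_um2", "perimeter_um")
  use <- if (all(alt_c %in% names(cells_raw))) alt_c else need_c
  missing_cols <- setdiff(use, names(cells_raw))
  if (length(missing_cols) > 0) {
    stop("cell table format error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  cells <- data.frame(
    cell_id = as.character(cells_raw[[use[1]]]),
    frame = as.integer(cells_raw[[use[2]]]),
    cx_um = as.numeric(cells_raw[[use[3]]]) * s,
    cy_um = as.numeric(cells_raw[[use[4]]]) * s,
    area_um2 = as.numeric(cells_raw[[use[5]]]) * s^2,
    perimeter_um = as.numeric(cells_raw[[use[6]]]) * s,
    stringsAsFactors = FALSE
  )
  if (any(cells$area_um2 <= 0) || any(cells$perimeter_um <= 0)) {
    stop("cell table validation error: non-positive area or perimeter", call. = FALSE)
  }

  bonds_raw <- tryCatch(read.csv(bond_path, stringsAsFactors = FALSE),
    error = function(e) data.frame()
  )
  if (nrow(bonds_raw) == 0) {
    warning("bond table is empty: topology/junction analyses will see no edges")
    bonds <- data.frame(
      frame = integer(0), cell_id_a = character(0),
      cell_id_b = character(0), length_um = numeric(0),
      stringsAsFactors = FALSE
    )
    bonds$polyline <- list()
  } else {
    need_b <- c("frame", "cell_id_a", "cell_id_b")
    missing_cols <- setdiff(need_b, names(bonds_raw))
    if (length(missing_cols) > 0) {
      stop("bond table format error: missing column(s) ",
        paste(missing_cols, collapse = ", "),
        call. = FALSE
      )
    }
    lcol <- if ("length_um" %in% names(bonds_raw)) "length_um" else "length"
    if (!lcol %in% names(bonds_raw)) {
      stop("bond table format error: missing column length_um", call. = FALSE)
    }
    bonds <- data.frame(
      frame = as.integer(bonds_raw$frame),
      cell_id_a = as.character(bonds_raw$cell_id_a),
      cell_id_b = as.character(bonds_raw$cell_id_b),
      length_um = as.numeric(bonds_raw[[lcol]]) * s,
      stringsAsFactors = FALSE
    )
    bonds$polyline <- if ("polyline" %in% names(bonds_raw)) {
      lapply(bonds_raw$polyline, parse_polyline, scale = s)
    } else {
      rep(list(NULL), nrow(bonds))
    }
    if (any(bonds$length_um <= 0)) {
      stop("bond table validation error: non-positive bond length", call. = FALSE)
    }
    if (any(bonds$cell_id_a == bonds$cell_id_b)) {
      stop("bond table validation error: bond joining a cell to itself", call. = FALSE)
    }
    cell_key <- paste(cells$cell_id, cells$frame)
    orphan <- !(paste(bonds$cell_id_a, bonds$frame) %in% cell_key) |
      !(paste(bonds$cell_id_b, bonds$frame) %in% cell_key)
    if (any(orphan)) {
      stop(
        "bond table validation error: bond(s) referencing absent cells at rows ",
        paste(which(orphan), collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(list(cells = cells, bonds = bonds), class = "cell_bond_tables")
}

parse_polyline <- function(s, scale = 1) {
  if (is.na(s) || !nzchar(s)) {
    return(NULL)
  }
  pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[ ,]+")
  m <- do.call(rbind, lapply(pts, as.numeric)) * scale
  colnames(m) <- c("x", "y")
  m
}

format_polyline <- function(m, digits = 6) {
  if (is.null(m)) {
    return("")
  }
  paste(apply(round(m, digits), 1, paste, collapse = " "), collapse = ";")
}

#' Write result tables and a run manifest
#'
#' Writes each named table as a TSV in `out_dir` plus a `manifest.json`
#' recording the configuration, seed and package version. Columns named with
#' an `_deg` suffix (or containing `angle`) are formatted with four decimal
#' places; re-running on identical input reproduces byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @param config optional [run_config()] stored in the manifest.
#' @param seed optional integer stored in the manifest.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    for (col in names(tab)) {
      if (grepl("_deg$|angle", col) && is.numeric(tab[[col]])) {
        tab[[col]] <- sprintf("%.4f", tab[[col]])
      }
      if (is.list(tab[[col]])) {
        tab[[col]] <- vapply(tab[[col]], format_polyline, character(1))
      }
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p,
      sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8"
    )
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "dyadrot",
    version = as.character(utils::packageVersion("dyadrot")),
    seed = seed,
    config = if (!is.null(config)) unclass(config) else NULL,
    tables = names(tables)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(c(paths, mp))
}

#' Write a track table in the CSV dialect consumed by [read_track_table()]
#'
#' @param tracks a `track_table`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_track_table <- function(tracks, path) {
  write.csv(as.data.frame(tracks)[, c("track_id", "frame", "time_min", "x_um", "y_um")],
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write cell/bond tables in the CSV dialect consumed by [read_cell_bond_tables()]
#'
#' @param tables a `cell_bond_tables`.
#' @param cell_path,bond_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_cell_bond_tables <- function(tables, cell_path, bond_path) {
  stopifnot(inherits(tables, "cell_bond_tables"))
  write.csv(tables$cells, cell_path, row.names = FALSE, quote = FALSE)
  b <- tables$bonds
  b$polyline <- vapply(b$polyline, format_polyline, character(1))
  write.csv(b, bond_path, row.names = FALSE, quote = FALSE)
  invisible(c(cell_path, bond_path))
}
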