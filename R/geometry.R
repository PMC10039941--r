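#' Electrode array geometry
#'
#' Describes a rectangular grid of recording electrodes with an optional
#' present/absent mask, e.g. the standard 96-channel Utah array: a 10 x 10
#' grid spanning 4 mm x 4 mm with the four corner positions unoccupied.
#'
#' Positions are 0-based `(row, col)` pairs internally. Spatial lags are
#' reported as `(xi, psi)` where `xi` is the column (x) lag and `psi` the row
#' (y) lag, both in electrode-pitch units; the lag origin `(0, 0)` maps to the
#' center of the `(2W - 1) x (2W - 1)` accumulation grid (1-based index
#' `(W, W)`, with `W = max(n_rows, n_cols)`).
#'
#' @param n_rows,n_cols Grid dimensions (each >= 2).
#' @param pitch_mm Electrode spacing in mm (> 0).
#' @param absent_positions Optional integer matrix or list of 0-based
#'   `(row, col)` pairs with no electrode.
#' @param channel_ids Optional channel ids assigned to present positions in
#'   row-major order; defaults to `1:n_present`.
#' @return An object of class `array_geometry` with fields `n_rows`, `n_cols`,
#'   `pitch_mm`, `present` (logical `n_rows x n_cols` matrix) and
#'   `channel_map` (data.frame `channel_id`, `row`, `col`; 0-based).
#' @examples
#' g <- mea_geometry()          # 96-channel Utah-style default
#' sum(g$present)               # 96
#' @export
array_geometry <- function(n_rows, n_cols, pitch_mm,
                           absent_positions = NULL, channel_ids = NULL) {
  stopifnot(n_rows >= 2, n_cols >= 2, pitch_mm > 0)
  present <- matrix(TRUE, n_rows, n_cols)
  if (!is.null(absent_positions)) {
    ap <- if (is.list(absent_positions)) {
      do.call(rbind, lapply(absent_positions, as.integer))
    } else {
      matrix(as.integer(absent_positions), ncol = 2)
    }
    if (any(ap[, 1] < 0 | ap[, 1] >= n_rows | ap[, 2] < 0 | ap[, 2] >= n_cols))
      stop("absent position outside the grid")
    present[cbind(ap[, 1] + 1L, ap[, 2] + 1L)] <- FALSE
  }
  pos <- which(t(present), arr.ind = TRUE)  # row-major enumeration
  cm <- data.frame(row = pos[, 2] - 1L, col = pos[, 1] - 1L)
  cm <- cm[order(cm$row, cm$col), , drop = FALSE]
  n_present <- nrow(cm)
  if (is.null(channel_ids)) channel_ids <- seq_len(n_present)
  if (length(channel_ids) != n_present || anyDuplicated(channel_ids))
    stop("channel_ids must be unique and match the number of present positions")
  geom <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    pitch_mm = pitch_mm, present = present,
    channel_map = data.frame(channel_id = channel_ids,
                             row = cm$row, col = cm$col)
  )
  class(geom) <- "array_geometry"
  geom
}

#' Default 96-channel Utah-style array geometry
#'
#' A 10 x 10 grid at 0.4 mm pitch with the four corner positions absent,
#' leaving 96 active channels across a 4 mm x 4 mm footprint.
#'
#' @param pitch_mm Electrode pitch, default 0.4 mm.
#' @return An `array_geometry`.
#' @export
mea_geometry <- function(pitch_mm = 0.4) {
  array_geometry(10, 10, pitch_mm,
                 absent_positions = rbind(c(0, 0), c(0, 9), c(9, 0), c(9, 9)))
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("array_geometry: %d x %d grid, pitch %g mm, %d present channels\n",
              x$n_rows, x$n_cols, x$pitch_mm, nrow(x$channel_map)))
  invisible(x)
}

#' Number of present channels
#' @param geometry An `array_geometry`.
#' @return Integer count.
#' @export
n_channels <- function(geometry) nrow(geometry$channel_map)

#' Half-width of the spatial lag grid
#'
#' `W = max(n_rows, n_cols)`; spatial lags run over `-(W-1) .. (W-1)` per axis
#' so the accumulation grid is `(2W - 1)` on a side (19 for a 10 x 10 array).
#' @param geometry An `array_geometry`.
#' @return Integer `W`.
#' @export
grid_halfwidth <- function(geometry) max(geometry$n_rows, geometry$n_cols)

# (row, col) position of each requested channel, 0-based, as a 2-col matrix
channel_positions <- function(geometry, channel_ids) {
  idx <- match(channel_ids, geometry$channel_map$channel_id)
  if (anyNA(idx)) stop("unknown channel id(s): ",
                       paste(channel_ids[is.na(idx)], collapse = ", "))
  cbind(row = geometry$channel_map$row[idx],
        col = geometry$channel_map$col[idx])
}

#' Spatial lag from a source channel to a target grid position
#'
#' @param source_channel Channel id of the reference (spike) electrode.
#' @param target_xy Target position as `(x, y)` = `(col, row)`, 0-based.
#' @param geometry An `array_geometry`.
#' @return Named numeric `(xi, psi)`: column and row lag in pitch units.
#' @export
lag_of <- function(source_channel, target_xy, geometry) {
  p <- channel_positions(geometry, source_channel)
  c(xi = unname(as.integer(target_xy[1]) - p[1, "col"]),
    psi = unname(as.integer(target_xy[2]) - p[1, "row"]))
}

#' Geometric contribution-count table over spatial lags
#'
#' For every spatial lag `(xi, psi)`, the number of present source channels
#' `c` such that `position(c) + (psi, xi)` is also a present position. When a
#' spike is recorded on each channel exactly once, this is exactly the count
#' tensor accumulated by the spike-centered average at each spatial lag (the
#' denominator `N` of the averaging step), so it serves as the independent
#' oracle for count accumulation. For a full `n x n` grid the table has the
#' separable closed form `(n - |xi|)(n - |psi|)`.
#'
#' @param geometry An `array_geometry`.
#' @return Integer matrix `(2W-1) x (2W-1)`; rows index `psi` (row lag) from
#'   `-(W-1)` to `W-1`, columns index `xi` likewise. `dimnames` carry the lags.
#' @export
offset_count_table <- function(geometry) {
  W <- grid_halfwidth(geometry)
  side <- 2L * W - 1L
  tab <- matrix(0L, side, side,
                dimnames = list(psi = as.character(-(W - 1):(W - 1)),
                                xi = as.character(-(W - 1):(W - 1))))
  pos <- channel_positions(geometry, geometry$channel_map$channel_id)
  pres <- geometry$present
  for (i in seq_len(nrow(pos))) {
    tr <- pos[, "row"] - pos[i, "row"]   # psi of every present target
    tc <- pos[, "col"] - pos[i, "col"]   # xi
    idx <- cbind(tr + W, tc + W)
    tab[idx] <- tab[idx] + 1L
  }
  tab
}

#' Spatial and temporal lag axes of an st-SCA tensor
#'
#' @param geometry An `array_geometry`.
#' @param n_lags Number of temporal lags on each side of zero (`n`), so the
#'   temporal axis has `2n + 1` samples.
#' @param frame_fs_hz Frame rate the temporal lags refer to.
#' @return List with `spatial_lags_px`, `spatial_lags_mm`,
#'   `temporal_lags_samples`, `temporal_lags_s`, and `origin_index`
#'   (1-based `(W, W, n + 1)`).
#' @export
lag_axes <- function(geometry, n_lags, frame_fs_hz) {
  W <- grid_halfwidth(geometry)
  px <- -(W - 1):(W - 1)
  ts <- -n_lags:n_lags
  list(spatial_lags_px = px,
       spatial_lags_mm = px * geometry$pitch_mm,
       temporal_lags_samples = ts,
       temporal_lags_s = ts / frame_fs_hz,
       origin_index = c(W, W, n_lags + 1L))
}

#' Write / read array geometry as JSON
#'
#' Layout: `{n_rows, n_cols, pitch_mm, absent_positions: [[r,c],...],
#' channel_map: [[id,r,c],...]}` with 0-based positions.
#' @param geometry An `array_geometry`.
#' @param path Output file.
#' @return `read_geometry_json` returns an `array_geometry`;
#'   `write_geometry_json` returns `path` invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  absent <- which(!geometry$present, arr.ind = TRUE)
  obj <- list(
    n_rows = geometry$n_rows, n_cols = geometry$n_cols,
    pitch_mm = geometry$pitch_mm,
    absent_positions = unname(apply(absent, 1, function(p)
      c(p[1] - 1L, p[2] - 1L), simplify = FALSE)),
    channel_map = unname(apply(geometry$channel_map, 1, as.integer,
                               simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_rows <- function(x, k) {       # list-of-tuples or already a matrix
    if (is.matrix(x)) x else matrix(unlist(x), ncol = k, byrow = TRUE)
  }
  cm <- as_rows(obj$channel_map, 3)
  absent <- if (length(obj$absent_positions))
    as_rows(obj$absent_positions, 2)
  array_geometry(obj$n_rows, obj$n_cols, obj$pitch_mm,
                 absent_positions = absent,
                 channel_ids = cm[order(cm[, 2], cm[, 3]), 1])
}
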