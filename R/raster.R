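#' Lightweight gridded surface
#'
#' A minimal matrix-backed raster used throughout the package for burn grids,
#' rainfall fields, utilization distributions and trend surfaces. Row `i` of
#' `values` spans y in `[ymin + (i-1)*pixel_size, ymin + i*pixel_size)` and
#' column `j` spans the analogous x interval: cells are half-open so every
#' point belongs to exactly one cell and boundary points are never
#' double-assigned.
#'
#' @param values numeric (or character, for categorical surfaces) matrix.
#' @param xmin,ymin map coordinates of the lower-left corner, metres.
#' @param pixel_size cell edge length, metres.
#' @return an object of class `fr_raster`.
#' @export
fr_raster <- function(values, xmin = 0, ymin = 0, pixel_size) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(
    list(values = values, xmin = xmin, ymin = ymin, pixel_size = pixel_size),
    class = "fr_raster"
  )
}

#' @export
print.fr_raster <- function(x, ...) {
  cat(sprintf(
    "<fr_raster> %d x %d cells, %g m pixels, origin (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$pixel_size, x$xmin, x$ymin
  ))
  invisible(x)
}

#' @export
dim.fr_raster <- function(x) dim(x$values)

#' Map coordinates to grid cells (half-open cell convention)
#'
#' @param r an [fr_raster()].
#' @param x,y coordinate vectors, metres.
#' @return a data.frame with columns `row`, `col`; an error if any point
#'   falls outside the grid.
#' @export
fr_cell_at <- function(r, x, y) {
  row <- floor((y - r$ymin) / r$pixel_size) + 1L
  col <- floor((x - r$xmin) / r$pixel_size) + 1L
  bad <- row < 1L | row > nrow(r$values) | col < 1L | col > ncol(r$values)
  if (any(bad)) {
    stop(sprintf(
      "point (%g, %g) falls outside the raster extent", x[bad][1], y[bad][1]
    ))
  }
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Value of the cell containing each point
#'
#' @inheritParams fr_cell_at
#' @return vector of cell values (NA where the cell holds nodata).
#' @export
fr_value_at <- function(r, x, y) {
  cells <- fr_cell_at(r, x, y)
  r$values[cbind(cells$row, cells$col)]
}

#' Cell-centre coordinates
#'
#' @param r an [fr_raster()].
#' @param row,col integer cell indices.
#' @return data.frame with columns `x`, `y` (metres).
#' @export
fr_cell_center <- function(r, row, col) {
  data.frame(
    x = r$xmin + (col - 0.5) * r$pixel_size,
    y = r$ymin + (row - 0.5) * r$pixel_size
  )
}

#' Long-format view of a raster
#'
#' @param r an [fr_raster()].
#' @param drop_na drop nodata cells.
#' @return data.frame with `row`, `col`, `x`, `y`, `value`.
#' @export
fr_as_df <- function(r, drop_na = TRUE) {
  idx <- which(!is.na(r$values) | !drop_na, arr.ind = TRUE)
  ctr <- fr_cell_center(r, idx[, 1], idx[, 2])
  data.frame(
    row = idx[, 1], col = idx[, 2], x = ctr$x, y = ctr$y,
    value = r$values[idx]
  )
}

#' Monthly gridded series (e.g. rainfall)
#'
#' A stack of monthly surfaces on a common grid, stored as a cells-by-month
#' array with a (year, month) time index.
#'
#' @param arr 3-d array `nrow x ncol x n_months`.
#' @param time data.frame with integer columns `year`, `month` (one row per
#'   slice of `arr`, chronological).
#' @param xmin,ymin,pixel_size grid geometry as in [fr_raster()].
#' @return an object of class `fr_series`.
#' @export
fr_series <- function(arr, time, xmin = 0, ymin = 0, pixel_size) {
  stopifnot(length(dim(arr)) == 3L, nrow(time) == dim(arr)[3])
  if (is.unsorted(time$year * 12L + time$month))
    stop("`time` must be chronological")
  structure(
    list(arr = arr, time = time, xmin = xmin, ymin = ymin,
         pixel_size = pixel_size),
    class = "fr_series"
  )
}

#' @export
print.fr_series <- function(x, ...) {
  cat(sprintf(
    "<fr_series> %d x %d cells, %d monthly slices (%d-%02d to %d-%02d)\n",
    dim(x$arr)[1], dim(x$arr)[2], nrow(x$time),
    x$time$year[1], x$time$month[1],
    x$time$year[nrow(x$time)], x$time$month[nrow(x$time)]
  ))
  invisible(x)
}

#' Extract one monthly slice of a series as a raster
#' @param s an [fr_series()].
#' @param year,month integers identifying the slice.
#' @return an [fr_raster()].
#' @export
fr_slice <- function(s, year, month) {
  k <- which(s$time$year == year & s$time$month == month)
  if (length(k) != 1L)
    stop(sprintf("series has no slice for %d-%02d", year, month))
  fr_raster(s$arr[, , k], s$xmin, s$ymin, s$pixel_size)
}

#' Series value at a point for a given month
#' @inheritParams fr_slice
#' @param x,y point coordinates, metres.
#' @export
fr_series_at <- function(s, x, y, year, month) {
  fr_value_at(fr_slice(s, year, month), x, y)
}
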