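# Plain-coordinate polygon helpers. Rings are two-column matrices (x, y),
# closed (first vertex repeated last). Enough geometry for rectangular
# management units and point-in-polygon assignment; no external GIS stack.

#' Build a closed rectangular ring
#' @param xmin,xmax,ymin,ymax rectangle bounds, metres.
#' @return closed two-column matrix of vertices.
#' @export
rect_ring <- function(xmin, xmax, ymin, ymax) {
  cbind(
    x = c(xmin, xmax, xmax, xmin, xmin),
    y = c(ymin, ymin, ymax, ymax, ymin)
  )
}

#' Signed polygon area (shoelace formula)
#' @param ring closed two-column vertex matrix.
#' @return area in the square of the coordinate unit (positive regardless of
#'   winding).
#' @export
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Point-in-polygon test (ray casting)
#'
#' Points exactly on an edge may be assigned to either side; management-unit
#' assignment therefore uses cell centres, which never lie on unit borders
#' for grid-aligned units.
#'
#' @param px,py point coordinate vectors.
#' @param ring closed two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x) - 1L
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Management units for a rectangular landscape
#'
#' Mirrors the structure of a multi-unit protected-area complex: a protected
#' interior tiled 2 x 4 into eight named units, surrounded by a buffer strip
#' where livestock keeping is unrestricted. Fire policies vary by unit
#' (suppression, active burning, communal burning) and the two easternmost
#' units permit livestock, giving the generators a management gradient to
#' imprint on boma densities.
#'
#' @param width_m,height_m landscape extent, metres.
#' @param buffer_m width of the buffer strip inside the landscape edge.
#' @return list of units; each unit is a list with `name`, `ring` (closed
#'   vertex matrix; the buffer's ring is the outer boundary), logical
#'   `livestock_permitted`, `fire_policy` and logical `is_buffer`.
#' @export
make_management_units <- function(width_m, height_m, buffer_m) {
  if (buffer_m * 2 >= min(width_m, height_m))
    stop("buffer too wide for the landscape")
  x0 <- buffer_m; x1 <- width_m - buffer_m
  y0 <- buffer_m; y1 <- height_m - buffer_m
  xs <- seq(x0, x1, length.out = 5L)
  ys <- seq(y0, y1, length.out = 3L)
  policies <- c("active_burn", "active_burn", "active_burn", "communal",
                "suppress", "active_burn", "communal", "communal")
  units <- list()
  k <- 0L
  for (i in 1:2) {
    for (j in 1:4) {
      k <- k + 1L
      units[[k]] <- list(
        name = sprintf("PA_%d", k),
        ring = rect_ring(xs[j], xs[j + 1], ys[i], ys[i + 1]),
        livestock_permitted = j == 4L,
        fire_policy = policies[k],
        is_buffer = FALSE
      )
    }
  }
  units[[k + 1L]] <- list(
    name = "buffer",
    ring = rect_ring(0, width_m, 0, height_m),
    livestock_permitted = TRUE,
    fire_policy = "communal",
    is_buffer = TRUE
  )
  names(units) <- vapply(units, `[[`, "", "name")
  units
}

#' Assign points to management units
#'
#' Protected units are checked first; points inside the landscape but in no
#' protected unit belong to the buffer. Points outside the landscape get NA.
#'
#' @param px,py point coordinates.
#' @param units unit list from [make_management_units()].
#' @return character vector of unit names.
#' @export
assign_unit <- function(px, py, units) {
  out <- rep(NA_character_, length(px))
  buffer_name <- NULL
  for (u in units) {
    if (u$is_buffer) {
      buffer_name <- u$name
      next
    }
    hit <- is.na(out) & point_in_polygon(px, py, u$ring)
    out[hit] <- u$name
  }
  if (!is.null(buffer_name)) {
    u <- units[[buffer_name]]
    hit <- is.na(out) & point_in_polygon(px, py, u$ring)
    out[hit] <- buffer_name
  }
  out
}

#' Areas of management units in km^2
#'
#' The buffer's area is the landscape area minus the protected units' areas
#' (units tile the region).
#'
#' @param units unit list from [make_management_units()].
#' @return named numeric vector, km^2.
#' @export
unit_areas_km2 <- function(units) {
  a <- vapply(units, function(u) polygon_area(u$ring) / 1e6, 0)
  buf <- vapply(units, `[[`, TRUE, "is_buffer")
  if (any(buf)) a[buf] <- a[buf] - sum(a[!buf])
  a
}
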