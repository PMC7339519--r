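# Raster grids on a local planar CRS. `values` is a matrix with row 1 the
# SOUTHERN row and column 1 the western column, so values[r, c] is the cell
# centred at (origin_x + (c - 0.5) * cell, origin_y + (r - 0.5) * cell).
# The Esri ASCII writer flips rows to the top-first order the format wants.

#' Construct a spatial grid
#'
#' @param values numeric (or integer) matrix, row 1 = southern row.
#' @param origin numeric length-2, (x, y) of the lower-left corner in metres.
#' @param cell_size cell edge length in metres.
#' @param classes optional character vector mapping integer codes to
#'   land-cover class names; its presence makes the grid categorical.
#' @return an object of class `spatial_grid` (and `landcover_grid` when
#'   `classes` is given, `terrain_grid` otherwise).
#' @export
spatial_grid <- function(values, origin = c(0, 0), cell_size = 25,
                         classes = NULL) {
  if (!is.matrix(values)) wa_stop("`values` must be a matrix")
  stopifnot_scalar_number(cell_size, "cell_size", positive = TRUE)
  if (length(origin) != 2L || !all(is.finite(origin))) {
    wa_stop("`origin` must be a finite (x, y) pair")
  }
  if (is.null(classes) && !all(is.finite(values) | is.na(values))) {
    wa_stop("grid values must be finite or NA")
  }
  g <- list(values = values, origin = as.numeric(origin),
            cell_size = as.numeric(cell_size), classes = classes)
  class(g) <- c(if (is.null(classes)) "terrain_grid" else "landcover_grid",
                "spatial_grid")
  g
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells, %g m cells, origin (%g, %g)\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  if (!is.null(x$classes)) cat("classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

grid_extent <- function(g) {
  c(xmin = g$origin[1], ymin = g$origin[2],
    xmax = g$origin[1] + ncol(g$values) * g$cell_size,
    ymax = g$origin[2] + nrow(g$values) * g$cell_size)
}

# column/row index of the cell containing points (clamped to grid)
grid_cell_index <- function(g, x, y, clamp = TRUE) {
  col <- floor((x - g$origin[1]) / g$cell_size) + 1
  row <- floor((y - g$origin[2]) / g$cell_size) + 1
  if (clamp) {
    col <- pmin(pmax(col, 1), ncol(g$values))
    row <- pmin(pmax(row, 1), nrow(g$values))
  }
  cbind(row = row, col = col)
}

point_in_grid <- function(g, x, y) {
  ext <- grid_extent(g)
  x >= ext["xmin"] & x <= ext["xmax"] & y >= ext["ymin"] & y <= ext["ymax"]
}

#' Nearest-cell lookup on a grid (vectorised)
#' @keywords internal
grid_value_at <- function(g, x, y) {
  idx <- grid_cell_index(g, x, y)
  g$values[cbind(idx[, "row"], idx[, "col"])]
}

#' Bilinear interpolation of a continuous grid (vectorised)
#'
#' Interpolates between cell centres; clamps to the border half-cell so any
#' point inside the grid extent is valid.
#' @keywords internal
grid_interp <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  # fractional cell-centre coordinates
  u <- (x - g$origin[1]) / g$cell_size - 0.5
  v <- (y - g$origin[2]) / g$cell_size - 0.5
  u <- pmin(pmax(u, 0), nc - 1)
  v <- pmin(pmax(v, 0), nr - 1)
  c0 <- pmin(floor(u) + 1, nc); c1 <- pmin(c0 + 1, nc)
  r0 <- pmin(floor(v) + 1, nr); r1 <- pmin(r0 + 1, nr)
  fu <- u - (c0 - 1); fv <- v - (r0 - 1)
  z00 <- g$values[cbind(r0, c0)]; z01 <- g$values[cbind(r0, c1)]
  z10 <- g$values[cbind(r1, c0)]; z11 <- g$values[cbind(r1, c1)]
  if (anyNA(c(z00, z01, z10, z11))) {
    wa_stop("interpolation touches NODATA cells")
  }
  (1 - fv) * ((1 - fu) * z00 + fu * z01) + fv * ((1 - fu) * z10 + fu * z11)
}
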