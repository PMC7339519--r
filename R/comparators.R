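# Baseline accessibility methods the pipeline benchmarks against: the
# Euclidean ("as the crow flies") constant-speed estimate and a
# friction-surface least-cost raster method, plus the mean absolute /
# relative difference statistics used to compare methods.

#' Euclidean travel time at constant speed
#'
#' @param origin,destination (x, y) points in metres (lists/rows with `x`,
#'   `y` also accepted).
#' @param speed_kmh assumed constant walking speed; 5 km/h is the
#'   conventional value.
#' @return time in minutes.
#' @export
euclidean_time <- function(origin, destination, speed_kmh = 5) {
  p <- site_xy(origin); q <- site_xy(destination)
  if (!all(is.finite(c(p, q)))) wa_stop("coordinates must be finite")
  stopifnot_scalar_number(speed_kmh, "speed_kmh", positive = TRUE)
  60 * (euclidean_dist(p, q) / 1000) / speed_kmh
}

site_xy <- function(s) {
  if (is.numeric(s) && length(s) == 2L) as.numeric(s)
  else c(as.numeric(s$x), as.numeric(s$y))
}

#' Default land-cover walking speeds for the friction surface (km/h)
#'
#' Stand-in values in the spirit of published least-cost speed tables:
#' paths/roads walk at 5 km/h, open savanna slightly slower, closed forest
#' and rice paddies slower still, water slowest.
#' @export
default_speed_table <- c(water = 0.5, forest = 3, rice_field = 2,
                         savanna = 4, residential = 4, other = 3,
                         path = 5)

#' Build a friction (cost) surface from land cover and the path network
#'
#' Every cell gets the base walking speed of its land-cover class; cells
#' crossed by a network edge are "burned" with the path speed, which
#' overrides the land-cover value.
#'
#' @param landcover a `landcover_grid`.
#' @param network optional `path_network` to burn in.
#' @param speed_table named km/h speeds covering every land-cover class
#'   (plus `path` when a network is given).
#' @return a `cost_surface` (a `spatial_grid` of base speeds with class
#'   `cost_surface` prepended).
#' @export
build_cost_surface <- function(landcover, network = NULL,
                               speed_table = default_speed_table) {
  missing_cls <- setdiff(landcover$classes, names(speed_table))
  if (length(missing_cls)) {
    wa_stop("speed_table lacks class(es): ", paste(missing_cls, collapse = ", "))
  }
  spd <- matrix(speed_table[landcover$classes[landcover$values]],
                nrow(landcover$values), ncol(landcover$values))
  if (any(spd <= 0)) wa_stop("base speeds must be > 0")
  if (!is.null(network)) {
    if (is.na(speed_table["path"])) wa_stop("speed_table lacks class(es): path")
    step <- landcover$cell_size / 2
    for (ge in network$geoms) {
      st <- sample_stations(polyline_length(ge), step)
      pts <- t(vapply(st, function(d) point_along(ge, d), numeric(2)))
      idx <- grid_cell_index(landcover, pts[, 1], pts[, 2])
      spd[unique(cbind(idx[, "row"], idx[, "col"]))] <- speed_table[["path"]]
    }
  }
  g <- spatial_grid(spd, origin = landcover$origin,
                    cell_size = landcover$cell_size)
  class(g) <- c("cost_surface", class(g))
  g
}

# Tobler-style anisotropic slope factor, normalised to 1 on flat ground;
# gradient g is signed rise/run in the direction of travel
slope_speed_factor <- function(gradient, anisotropic = TRUE) {
  if (!anisotropic) gradient <- abs(gradient)
  exp(-3.5 * abs(gradient + 0.05)) / exp(-0.175)
}

#' Least-cost travel time over a friction surface
#'
#' Dijkstra over the 8-connected cell graph. A step between adjacent cells
#' costs `step_length / (base_speed * slope_factor)` minutes, with the base
#' speed the mean of the two cells and a Tobler-style anisotropic slope
#' correction (downhill-tolerant, normalised to 1 on flat ground);
#' `anisotropic = FALSE` uses the symmetric |gradient| version. Diagonal
#' steps are sqrt(2) cell lengths.
#'
#' @param cost_surface a `cost_surface` (km/h per cell).
#' @param terrain matching `terrain_grid` (set `NULL` to ignore slope).
#' @param origin (x, y) origin point.
#' @param destinations matrix / data frame of destination points (x, y).
#' @param anisotropic use the direction-aware slope factor.
#' @return minutes to the nearest destination.
#' @export
least_cost_time <- function(cost_surface, terrain, origin, destinations,
                            anisotropic = TRUE) {
  o <- site_xy(origin)
  dst <- as.matrix(if (is.data.frame(destinations))
    destinations[, c("x", "y")] else destinations)
  if (!point_in_grid(cost_surface, o[1], o[2])) wa_stop("origin outside grid")
  if (!all(point_in_grid(cost_surface, dst[, 1], dst[, 2]))) {
    wa_stop("destination outside grid")
  }
  if (anyNA(grid_value_at(cost_surface, o[1], o[2]))) {
    wa_stop("origin lies on a NODATA cell")
  }
  g <- cell_graph(cost_surface, terrain, anisotropic)
  nr <- nrow(cost_surface$values)
  vid <- function(p) {
    ix <- grid_cell_index(cost_surface, p[1], p[2])
    (ix[, "col"] - 1) * nr + ix[, "row"]
  }
  ov <- vid(o)
  dv <- unique(vapply(seq_len(nrow(dst)), function(i) vid(dst[i, ]), numeric(1)))
  d <- igraph::distances(g, v = as.character(ov), to = as.character(dv),
                         mode = "out")
  min(d)
}

# directed igraph over 8-connected cells; weights in minutes
cell_graph <- function(cost_surface, terrain, anisotropic = TRUE) {
  spd <- cost_surface$values
  nr <- nrow(spd); nc <- ncol(spd)
  cs <- cost_surface$cell_size
  id <- matrix(seq_len(nr * nc), nr, nc) # column-major cell ids
  moves <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  elev <- if (!is.null(terrain)) terrain$values else NULL
  for (mv in moves) {
    dr <- mv[1]; dc <- mv[2]
    r0 <- max(1, 1 - dr):min(nr, nr - dr)
    c0 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- id[r0, c0, drop = FALSE]
    b <- id[r0 + dr, c0 + dc, drop = FALSE]
    step <- cs * sqrt(dr^2 + dc^2)
    v_ab <- (spd[a] + spd[b]) / 2
    ok <- is.finite(v_ab) & v_ab > 0
    fac <- if (is.null(elev)) 1 else
      slope_speed_factor((elev[b] - elev[a]) / step, anisotropic)
    wt <- (step / 1000) / (v_ab * fac) * 60
    from <- c(from, a[ok]); to <- c(to, b[ok]); w <- c(w, wt[ok])
  }
  igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to), weight = w),
    directed = TRUE,
    vertices = data.frame(name = as.character(seq_len(nr * nc)))
  )
}

#' Compare travel-time methods against a reference
#'
#' Per route, the absolute difference `|t_m - t_ref|` (minutes) and the
#' relative difference `100 * |t_m - t_ref| / t_ref` (%) are averaged;
#' absolute values keep under- and over-estimation from cancelling. Routes
#' with `t_ref = 0` are excluded from the relative mean and counted.
#'
#' @param reference named numeric of reference times (minutes), names =
#'   route ids.
#' @param methods named list of same-shape numeric vectors, one per
#'   method.
#' @return a `comparison_result`: `table` (method, mean_abs_diff_min,
#'   mean_rel_diff_pct, n, n_excluded_relative) and `signed` (per-route
#'   signed differences for histogramming).
#' @export
compare_methods <- function(reference, methods) {
  if (is.null(names(reference))) {
    names(reference) <- as.character(seq_along(reference))
  }
  rows <- list(); signed <- list()
  for (nm in names(methods)) {
    tm <- methods[[nm]]
    if (!is.null(names(tm))) tm <- tm[names(reference)]
    if (length(tm) != length(reference) || anyNA(tm)) {
      wa_stop("method '", nm, "' is not aligned with the reference routes")
    }
    dif <- tm - reference
    ok_rel <- reference > 0
    rows[[nm]] <- data.frame(
      method = nm,
      mean_abs_diff_min = mean(abs(dif)),
      mean_rel_diff_pct = if (any(ok_rel))
        mean(100 * abs(dif[ok_rel]) / reference[ok_rel]) else NA_real_,
      n = length(dif),
      n_excluded_relative = sum(!ok_rel),
      stringsAsFactors = FALSE
    )
    signed[[nm]] <- stats::setNames(dif, names(reference))
  }
  out <- list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
              signed = signed)
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  print(x$table)
  invisible(x)
}
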