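# Planar polyline primitives. A polyline is an n x 2 numeric matrix of
# (x, y) vertices in metres, local Cartesian coordinates, n >= 2 unless
# stated otherwise. All routing, segmentation and track machinery sits on
# these few functions, so they are deliberately small and heavily tested.

as_polyline <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2L || nrow(m) < 1L || !all(is.finite(m))) {
    wa_stop("a polyline must be a finite n x 2 coordinate matrix")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' Arc length of a polyline
#' @param pl n x 2 coordinate matrix.
#' @return total length in metres.
#' @keywords internal
polyline_length <- function(pl) {
  pl <- as_polyline(pl)
  if (nrow(pl) < 2L) return(0)
  sum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2))
}

# cumulative arc length at each vertex (first element 0)
polyline_cumlen <- function(pl) {
  pl <- as_polyline(pl)
  if (nrow(pl) < 2L) return(0)
  c(0, cumsum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2)))
}

#' Point at a given arc-length station along a polyline
#' @keywords internal
point_along <- function(pl, d) {
  pl <- as_polyline(pl)
  cl <- polyline_cumlen(pl)
  total <- cl[length(cl)]
  d <- min(max(d, 0), total)
  i <- findInterval(d, cl, rightmost.closed = TRUE)
  i <- min(i, nrow(pl) - 1L)
  seg <- cl[i + 1L] - cl[i]
  f <- if (seg > 0) (d - cl[i]) / seg else 0
  pl[i, ] + f * (pl[i + 1L, ] - pl[i, ])
}

#' Sub-polyline between two arc-length stations
#'
#' Returns the piece of `pl` between stations `d0 <= d1`; endpoints are
#' interpolated so that concatenating adjacent pieces reproduces `pl`
#' exactly (up to repeated joint vertices).
#' @keywords internal
sub_polyline <- function(pl, d0, d1) {
  pl <- as_polyline(pl)
  cl <- polyline_cumlen(pl)
  total <- cl[length(cl)]
  d0 <- min(max(d0, 0), total)
  d1 <- min(max(d1, 0), total)
  if (d1 < d0) wa_stop("sub_polyline: d1 < d0")
  p0 <- point_along(pl, d0)
  p1 <- point_along(pl, d1)
  inner <- which(cl > d0 & cl < d1)
  out <- rbind(p0, if (length(inner)) pl[inner, , drop = FALSE], p1)
  as_polyline(out)
}

# reverse vertex order
rev_polyline <- function(pl) {
  pl <- as_polyline(pl)
  pl[rev(seq_len(nrow(pl))), , drop = FALSE]
}

#' Project a point onto a polyline
#'
#' @param pl polyline.
#' @param p length-2 numeric point.
#' @return list with `station` (arc length of nearest point), `dist`
#'   (offset distance) and `point` (the nearest point itself).
#' @keywords internal
project_point <- function(pl, p) {
  pl <- as_polyline(pl)
  if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p))) {
    wa_stop("`p` must be a finite (x, y) point")
  }
  n <- nrow(pl)
  if (n == 1L) {
    return(list(station = 0, dist = sqrt(sum((pl[1, ] - p)^2)), point = pl[1, ]))
  }
  ax <- pl[-n, 1]; ay <- pl[-n, 2]
  bx <- pl[-1, 1]; by <- pl[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((p[1] - ax) * dx + (p[2] - ay) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * dx; qy <- ay + t * dy
  d2 <- (qx - p[1])^2 + (qy - p[2])^2
  i <- which.min(d2)
  cl <- polyline_cumlen(pl)
  list(
    station = unname(cl[i] + t[i] * sqrt(len2[i])),
    dist = unname(sqrt(d2[i])),
    point = c(x = unname(qx[i]), y = unname(qy[i]))
  )
}

#' Points at many arc-length stations (vectorised [point_along()])
#' @keywords internal
points_along <- function(pl, stations) {
  pl <- as_polyline(pl)
  cl <- polyline_cumlen(pl)
  total <- cl[length(cl)]
  s <- pmin(pmax(stations, 0), total)
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(pl) - 1L)
  seg <- cl[i + 1L] - cl[i]
  f <- ifelse(seg > 0, (s - cl[i]) / seg, 0)
  cbind(x = pl[i, 1] + f * (pl[i + 1L, 1] - pl[i, 1]),
        y = pl[i, 2] + f * (pl[i + 1L, 2] - pl[i, 2]))
}

# stations (arc lengths) at fixed spacing, always including 0 and total
sample_stations <- function(total, step) {
  if (total <= 0) return(c(0, 0))
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  s
}

euclidean_dist <- function(a, b) {
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2)
}
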