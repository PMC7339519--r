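# Route/track segmentation: split a polyline into 100 m pieces, attach the
# covariates the speed model consumes (slope %, land-cover label,
# cumulative-distance category, rainfall), and turn GPS tracks into
# point-pair speed observations.

#' Split a polyline into fixed-length segments
#'
#' All pieces are exactly `step_m` long except the last, which takes the
#' remainder. Concatenating the pieces reproduces the parent polyline.
#'
#' @param polyline n x 2 coordinate matrix of positive length.
#' @param step_m segment length in metres (100 m mirrors the field
#'   protocol).
#' @return list of segments, each a list with `index`, `start_m`, `end_m`,
#'   `polyline`.
#' @export
split_polyline <- function(polyline, step_m = 100) {
  polyline <- as_polyline(polyline)
  total <- polyline_length(polyline)
  if (total <= 0) wa_stop("cannot split a zero-length polyline")
  stopifnot_scalar_number(step_m, "step_m", positive = TRUE)
  starts <- seq(0, total, by = step_m)
  if (starts[length(starts)] >= total) starts <- starts[-length(starts)]
  ends <- pmin(starts + step_m, total)
  lapply(seq_along(starts), function(i) {
    list(index = i, start_m = starts[i], end_m = ends[i],
         polyline = sub_polyline(polyline, starts[i], ends[i]))
  })
}

#' Attach model covariates to a segment
#'
#' Slope is the signed percent grade along the direction of travel, from
#' bilinearly interpolated endpoint elevations. The land-cover label is the
#' class covering the largest share of the segment's length, or `"mixed"`
#' when that share is below 50% (cells of class `"other"`, which the speed
#' model has no term for, also fall back to `"mixed"`). The
#' cumulative-distance category switches to `"long"` when the segment
#' midpoint lies beyond 13 km from the journey origin.
#'
#' @param segment element of [split_polyline()] output.
#' @param terrain `terrain_grid`.
#' @param landcover `landcover_grid`.
#' @param rainfall_mm daily rainfall carried by the parent route/track.
#' @param cumdist_offset_m distance already walked before this polyline
#'   started (0 for routes measured from the household door).
#' @return the segment with `slope_pct`, `landcover_label`,
#'   `cumdist_category`, `rainfall_mm` filled in.
#' @export
attribute_covariates <- function(segment, terrain, landcover, rainfall_mm = 0,
                                 cumdist_offset_m = 0) {
  pl <- segment$polyline
  if (!all(point_in_grid(terrain, pl[, 1], pl[, 2])) ||
      !all(point_in_grid(landcover, pl[, 1], pl[, 2]))) {
    wa_stop("segment lies outside the raster extent")
  }
  len <- segment$end_m - segment$start_m
  p0 <- pl[1, ]; p1 <- pl[nrow(pl), ]
  z <- grid_interp(terrain, unname(c(p0[1], p1[1])), unname(c(p0[2], p1[2])))
  slope <- if (len > 0) unname(100 * (z[2] - z[1]) / len) else 0
  segment$slope_pct <- slope
  segment$landcover_label <- segment_landcover_label(pl, landcover)
  mid <- cumdist_offset_m + (segment$start_m + segment$end_m) / 2
  segment$cumdist_category <- if (mid > 13000) "long" else "short"
  segment$rainfall_mm <- rainfall_mm
  segment
}

# predominant land-cover label of a polyline, "mixed" if < 50% coverage
segment_landcover_label <- function(pl, landcover) {
  total <- polyline_length(pl)
  m <- max(20L, ceiling(total / (landcover$cell_size / 2)))
  st <- (seq_len(m) - 0.5) / m * total
  pts <- t(vapply(st, function(d) point_along(pl, d), numeric(2)))
  codes <- grid_value_at(landcover, pts[, 1], pts[, 2])
  tab <- tabulate(codes, nbins = length(landcover$classes))
  top <- which.max(tab)
  frac <- tab[top] / sum(tab)
  cls <- landcover$classes[top]
  if (frac < 0.5 || !(cls %in% segment_lc_labels)) "mixed" else cls
}

#' Segment a whole route and attribute covariates in one pass
#'
#' @inheritParams attribute_covariates
#' @param polyline route/track geometry.
#' @param step_m segment length.
#' @return data frame with one row per segment: `index`, `start_m`,
#'   `end_m`, `length_m`, `slope_pct`, `landcover_label`,
#'   `cumdist_category`, `rainfall_mm`.
#' @export
segment_route <- function(polyline, terrain, landcover, rainfall_mm = 0,
                          step_m = 100, cumdist_offset_m = 0) {
  polyline <- as_polyline(polyline)
  if (!all(point_in_grid(terrain, polyline[, 1], polyline[, 2])) ||
      !all(point_in_grid(landcover, polyline[, 1], polyline[, 2]))) {
    wa_stop("segment lies outside the raster extent")
  }
  total <- polyline_length(polyline)
  if (total <= 0) wa_stop("cannot split a zero-length polyline")
  starts <- seq(0, total, by = step_m)
  if (starts[length(starts)] >= total) starts <- starts[-length(starts)]
  ends <- pmin(starts + step_m, total)
  lens <- ends - starts
  nseg <- length(starts)
  # endpoint elevations -> signed slope along travel direction
  bpts <- points_along(polyline, c(starts, ends[nseg]))
  z <- grid_interp(terrain, bpts[, "x"], bpts[, "y"])
  slope <- ifelse(lens > 0, 100 * diff(z) / lens, 0)
  # land-cover label: same per-segment midpoint-sampling scheme as
  # attribute_covariates, batched over all segments
  m_k <- pmax(20L, ceiling(lens / (landcover$cell_size / 2)))
  seg_of <- rep.int(seq_len(nseg), m_k)
  offs <- (unlist(lapply(m_k, seq_len)) - 0.5) / rep.int(m_k, m_k)
  st <- starts[seg_of] + offs * lens[seg_of]
  spts <- points_along(polyline, st)
  codes <- grid_value_at(landcover, spts[, "x"], spts[, "y"])
  counts <- matrix(0L, nseg, length(landcover$classes))
  tab <- table(seg_of, factor(codes, levels = seq_along(landcover$classes)))
  counts[as.integer(rownames(tab)), ] <- as.integer(tab)
  top <- max.col(counts, ties.method = "first")
  frac <- counts[cbind(seq_len(nseg), top)] / rowSums(counts)
  cls <- landcover$classes[top]
  label <- ifelse(frac < 0.5 | !(cls %in% segment_lc_labels), "mixed", cls)
  mid <- cumdist_offset_m + (starts + ends) / 2
  data.frame(index = seq_len(nseg), start_m = starts, end_m = ends,
             length_m = lens, slope_pct = slope,
             landcover_label = label,
             cumdist_category = ifelse(mid > 13000, "long", "short"),
             rainfall_mm = rainfall_mm, stringsAsFactors = FALSE)
}

#' Point-pair speed observations from a GPS track
#'
#' Speed between consecutive points is planar distance over elapsed time.
#' Each pair inherits the covariates of the 100 m segment containing its
#' midpoint (by cumulative distance along the track). Pairs are dropped —
#' and counted, see `attr(, "filtered")` — when the elapsed time falls
#' outside `dt_nominal +/- dt_tol` (GPS dropouts), when the implied speed
#' exceeds `speed_ceiling` (3 m/s is already implausible on foot; faster
#' pairs are glitches), or when the two points coincide.
#'
#' @param track list with `track_id`, `individual_class`, `rainfall_mm` and
#'   `points` (data frame `t`, `x`, `y`, `ele`).
#' @param terrain,landcover district rasters.
#' @param speed_ceiling km/h filter ceiling.
#' @param dt_nominal,dt_tol accepted elapsed-time window in seconds.
#' @return data frame of `PairObservation`s: `track_id`,
#'   `individual_class`, `speed_kmh`, `slope_pct`, `landcover_label`,
#'   `cumdist_category`, `rainfall_mm`.
#' @export
pair_speeds <- function(track, terrain, landcover, speed_ceiling = 10.8,
                        dt_nominal = 10, dt_tol = 2) {
  pts <- track$points
  if (is.null(pts) || nrow(pts) < 2L) {
    wa_stop("track ", track$track_id, ": need at least two points")
  }
  if (any(diff(pts$t) <= 0)) {
    wa_stop("track ", track$track_id, ": timestamps are not strictly increasing")
  }
  pl <- as_polyline(cbind(pts$x, pts$y))
  dt <- diff(pts$t)
  dd <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
  speed <- dd / dt * 3.6
  cl <- c(0, cumsum(dd))
  mid <- (cl[-length(cl)] + cl[-1]) / 2

  keep_dt <- abs(dt - dt_nominal) <= dt_tol
  keep_move <- dd > 0
  keep_speed <- speed <= speed_ceiling
  keep <- keep_dt & keep_move & keep_speed
  filtered <- c(bad_dt = sum(!keep_dt),
                stationary = sum(keep_dt & !keep_move),
                too_fast = sum(keep_dt & keep_move & !keep_speed))

  segs <- segment_route(pl, terrain, landcover,
                        rainfall_mm = track$rainfall_mm)
  seg_idx <- findInterval(mid, segs$start_m)
  seg_idx <- pmin(pmax(seg_idx, 1L), nrow(segs))

  out <- data.frame(
    track_id = track$track_id,
    individual_class = track$individual_class,
    speed_kmh = speed,
    slope_pct = segs$slope_pct[seg_idx],
    landcover_label = segs$landcover_label[seg_idx],
    cumdist_category = segs$cumdist_category[seg_idx],
    rainfall_mm = track$rainfall_mm,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filtered") <- filtered
  out
}

#' Pair observations for a whole track set
#'
#' @param tracks a `track_set` (or plain list of tracks).
#' @inheritParams pair_speeds
#' @return row-bound [pair_speeds()] output with a combined `filtered`
#'   attribute.
#' @export
track_set_pairs <- function(tracks, terrain, landcover, speed_ceiling = 10.8,
                            dt_nominal = 10, dt_tol = 2) {
  trk <- if (inherits(tracks, "track_set")) tracks$tracks else tracks
  parts <- lapply(trk, pair_speeds, terrain = terrain, landcover = landcover,
                  speed_ceiling = speed_ceiling, dt_nominal = dt_nominal,
                  dt_tol = dt_tol)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "filtered") <- Reduce(`+`, lapply(parts, attr, "filtered"))
  out
}
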