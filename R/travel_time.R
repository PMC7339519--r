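# Door-to-facility travel time: segment-wise speed evaluation along the
# distance-shortest route, accumulated as sum(length / speed). Rainfall is
# scenario-constant over a route (daily rainfall rasters are far coarser
# than any route), and cumulative distance for the fatigue category is
# measured from the route origin, i.e. the household door.

#' Predict travel time along a route for one rainfall scenario
#'
#' @param route a `route` (or any object with `polyline`; a bare polyline
#'   matrix also works).
#' @param model a `speed_model`.
#' @param terrain,landcover district rasters.
#' @param rainfall_mm scenario rainfall (constant along the route).
#' @param individual_class walker class used for prediction; population
#'   predictions default to the reference class so they carry no walker
#'   premium.
#' @param cumdist_offset_m distance already walked before this route
#'   begins (for chained journeys).
#' @return a `time_prediction`: `route_id`, `rainfall_mm`, `time_min`,
#'   `length_m` and a `per_segment` data frame (length, speed, time per
#'   segment).
#' @export
predict_route_time <- function(route, model, terrain, landcover,
                               rainfall_mm = 0,
                               individual_class = "community_staff",
                               cumdist_offset_m = 0) {
  pl <- if (is.matrix(route)) route else route$polyline
  if (is.null(pl)) wa_stop("route has no geometry (disconnected building?)")
  route_id <- if (is.matrix(route)) NA_character_ else
    paste0(route$origin_id, "->", route$dest_id)
  segs <- segment_route(pl, terrain, landcover, rainfall_mm = rainfall_mm,
                        cumdist_offset_m = cumdist_offset_m)
  speed <- predict_speed(model,
                         slope_pct = segs$slope_pct,
                         rainfall_mm = segs$rainfall_mm,
                         cumdist_category = segs$cumdist_category,
                         landcover_label = segs$landcover_label,
                         individual_class = individual_class)
  time_min <- segs$length_m / 1000 / speed * 60
  out <- list(route_id = route_id, rainfall_mm = rainfall_mm,
              individual_class = individual_class,
              length_m = sum(segs$length_m),
              time_min = sum(time_min),
              per_segment = cbind(segs, speed_kmh = speed,
                                  time_min = time_min))
  class(out) <- "time_prediction"
  out
}

#' @export
print.time_prediction <- function(x, ...) {
  cat(sprintf("<time_prediction> %s: %.2f km in %.1f min at %.1f mm rainfall\n",
              x$route_id, x$length_m / 1000, x$time_min, x$rainfall_mm))
  invisible(x)
}

#' Dry and maximum-rainfall scenario times for a set of routes
#'
#' @param routes list of `route` objects (e.g.
#'   [nearest_facility_routes()] output).
#' @param model a `speed_model`.
#' @param terrain,landcover district rasters.
#' @param rain_max_mm rainy-scenario ceiling (mm/day); 47.5 mm is the
#'   largest daily rainfall seen during fieldwork.
#' @param individual_class walker class for prediction.
#' @return data frame with `route_id`, `origin_id`, `facility_kind`,
#'   `facility_id`, `distance_m`, `time_dry_min`, `time_rain_min`,
#'   `rainfall_scenario_mm`. Disconnected routes propagate as `Inf` times.
#' @export
scenario_times <- function(routes, model, terrain, landcover,
                           rain_max_mm = 47.5,
                           individual_class = "community_staff") {
  rows <- lapply(routes, function(r) {
    kind <- if (!is.null(r$facility_kind)) r$facility_kind else NA_character_
    fid <- if (!is.null(r$facility_id)) r$facility_id else
      as.character(r$dest_id)
    if (is.null(r$polyline) || !is.finite(r$length_m)) {
      return(data.frame(route_id = paste0(r$origin_id, "->", fid),
                        origin_id = as.character(r$origin_id),
                        facility_kind = kind, facility_id = fid,
                        distance_m = Inf, time_dry_min = Inf,
                        time_rain_min = Inf,
                        rainfall_scenario_mm = rain_max_mm,
                        stringsAsFactors = FALSE))
    }
    if (r$length_m == 0) {
      return(data.frame(route_id = paste0(r$origin_id, "->", fid),
                        origin_id = as.character(r$origin_id),
                        facility_kind = kind, facility_id = fid,
                        distance_m = 0, time_dry_min = 0, time_rain_min = 0,
                        rainfall_scenario_mm = rain_max_mm,
                        stringsAsFactors = FALSE))
    }
    dry <- predict_route_time(r, model, terrain, landcover, rainfall_mm = 0,
                              individual_class = individual_class)
    wet <- predict_route_time(r, model, terrain, landcover,
                              rainfall_mm = rain_max_mm,
                              individual_class = individual_class)
    data.frame(route_id = dry$route_id,
               origin_id = as.character(r$origin_id),
               facility_kind = kind, facility_id = fid,
               distance_m = dry$length_m,
               time_dry_min = dry$time_min,
               time_rain_min = wet$time_min,
               rainfall_scenario_mm = rain_max_mm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
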