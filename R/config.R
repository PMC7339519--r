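# District configuration: the "stated world" every synthetic artifact is
# drawn from. Defaults emulate a mountainous rural district of roughly
# 10 x 10 km with sparse facilities, footpath-only connectivity and a
# savanna-dominated land-cover mosaic.

#' Land-cover raster class codes
#'
#' The raster carries six classes; `mixed` is NOT a raster class — it is a
#' segment-level label assigned when no single class covers at least half of
#' a 100 m segment.
#' @export
lc_classes <- c("water", "forest", "rice_field", "savanna", "residential",
                "other")

#' Segment-level land-cover labels (raster classes plus `mixed`)
#' @export
segment_lc_labels <- c("water", "forest", "rice_field", "savanna",
                       "residential", "mixed")

#' Individual (walker) classes
#' @export
individual_classes <- c("community_staff", "research_team",
                        "local_population")

#' Build a synthetic-district configuration
#'
#' @param grid_size cells per side of the square rasters (>= 50).
#' @param cell_size metres per raster cell.
#' @param n_clusters number of residential clusters (villages).
#' @param buildings_per_cluster mean buildings per cluster; each cluster
#'   draws `4 + rpois(mean - 4)` buildings, so clusters always have the four
#'   buildings that define a residential area.
#' @param n_phc number of primary health care centres.
#' @param n_chs number of community health sites.
#' @param terrain_relief maximum elevation amplitude in metres.
#' @param landcover_fractions named numeric over [lc_classes] summing to 1.
#' @param rainfall_max maximum daily rainfall in mm (scenario ceiling and
#'   upper bound of the per-track rainfall draw).
#' @param seed integer seed; every generator derives its stream from it.
#' @return a `district_config` list.
#' @export
district_config <- function(grid_size = 400,
                            cell_size = 25,
                            n_clusters = 40,
                            buildings_per_cluster = 14,
                            n_phc = 3,
                            n_chs = 12,
                            terrain_relief = 500,
                            landcover_fractions = c(
                              water = 0.03, forest = 0.22, rice_field = 0.10,
                              savanna = 0.55, residential = 0.07, other = 0.03
                            ),
                            rainfall_max = 47.5,
                            seed = 1L) {
  stopifnot_scalar_number(grid_size, "grid_size")
  if (grid_size < 50) wa_stop("`grid_size` must be >= 50")
  stopifnot_scalar_number(cell_size, "cell_size", positive = TRUE)
  stopifnot_scalar_number(n_clusters, "n_clusters", positive = TRUE)
  stopifnot_scalar_number(buildings_per_cluster, "buildings_per_cluster",
                          positive = TRUE)
  stopifnot_scalar_number(n_phc, "n_phc")
  stopifnot_scalar_number(n_chs, "n_chs")
  if (n_phc < 1 || n_chs < 1) wa_stop("need at least one PHC and one CHS")
  stopifnot_scalar_number(terrain_relief, "terrain_relief")
  if (terrain_relief < 0) wa_stop("`terrain_relief` must be >= 0")
  stopifnot_scalar_number(rainfall_max, "rainfall_max")
  if (rainfall_max < 0) wa_stop("`rainfall_max` must be >= 0")
  if (is.null(names(landcover_fractions)) ||
      !setequal(names(landcover_fractions), lc_classes)) {
    wa_stop("`landcover_fractions` must be named over: ",
            paste(lc_classes, collapse = ", "))
  }
  landcover_fractions <- landcover_fractions[lc_classes]
  if (any(landcover_fractions < 0)) wa_stop("land-cover fractions must be >= 0")
  if (abs(sum(landcover_fractions) - 1) > 1e-9) {
    wa_stop("`landcover_fractions` must sum to 1 (got ",
            format(sum(landcover_fractions)), ")")
  }
  cfg <- list(
    grid_size = as.integer(grid_size),
    cell_size = as.numeric(cell_size),
    n_clusters = as.integer(n_clusters),
    buildings_per_cluster = as.numeric(buildings_per_cluster),
    n_phc = as.integer(n_phc),
    n_chs = as.integer(n_chs),
    terrain_relief = as.numeric(terrain_relief),
    landcover_fractions = landcover_fractions,
    rainfall_max = as.numeric(rainfall_max),
    seed = as.integer(seed)
  )
  class(cfg) <- "district_config"
  cfg
}

#' @export
print.district_config <- function(x, ...) {
  cat(sprintf(
    "<district_config> %d x %d cells of %g m (%.1f km side), %d clusters, %d PHC, %d CHS, seed %d\n",
    x$grid_size, x$grid_size, x$cell_size,
    x$grid_size * x$cell_size / 1000, x$n_clusters, x$n_phc, x$n_chs, x$seed))
  invisible(x)
}
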