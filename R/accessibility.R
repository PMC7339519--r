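# Population-level accessibility products: distance/time bin tables,
# dual-vulnerability site identification (households more than a threshold
# from BOTH facility kinds), and an inverse-distance-weighted surface for
# visualisation.

#' Default distance bin edges (km)
#' @export
distance_bins_km <- c(0, 1, 2, 5, 10, 20, 30)

#' Default travel-time bin edges (minutes; last bin open-ended)
#' @export
time_bins_min <- c(0, 30, 60, 120, 180, 240, Inf)

#' Bin a population by an accessibility value
#'
#' First bin is closed on both sides, subsequent bins are left-open /
#' right-closed, matching the conventional `[0, 1] (1, 2] ...` table
#' layout. A value falling outside every bin is an error — extend the last
#' edge (e.g. with `Inf`) explicitly instead.
#'
#' @param values numeric accessibility value per site (distance km, time
#'   min, ...).
#' @param edges increasing numeric bin edges (length = bins + 1).
#' @param weights non-negative population weights (default 1 per site —
#'   population is inferred from building counts).
#' @param facility_kind,metric,scenario metadata recorded on the table.
#' @return an `accessibility_table`: data frame `bin`, `lower`, `upper`,
#'   `population_pct`, `weight` with the metadata as attributes.
#' @export
bin_population <- function(values, edges, weights = rep(1, length(values)),
                           facility_kind = NA_character_,
                           metric = NA_character_,
                           scenario = NA_character_) {
  if (length(weights) != length(values)) wa_stop("one weight per value required")
  if (any(weights < 0) || sum(weights) <= 0) {
    wa_stop("weights must be >= 0 with positive total")
  }
  if (is.unsorted(edges, strictly = TRUE)) wa_stop("`edges` must be strictly increasing")
  if (any(values < edges[1] | values > edges[length(edges)])) {
    wa_stop("value(s) outside the binning range [", edges[1], ", ",
            edges[length(edges)], "]; extend the last bin explicitly")
  }
  idx <- cut(values, breaks = edges, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  w <- vapply(seq_len(length(edges) - 1L),
              function(b) sum(weights[idx == b]), numeric(1))
  lab <- c(sprintf("[%g, %g]", edges[1], edges[2]),
           sprintf("(%g, %g]", edges[-c(1, length(edges))], edges[-(1:2)]))
  lab[is.infinite(edges[-1])] <- sprintf("> %g", edges[length(edges) - 1L])
  tab <- data.frame(bin = lab, lower = edges[-length(edges)],
                    upper = edges[-1], population_pct = 100 * w / sum(w),
                    weight = w, stringsAsFactors = FALSE)
  attr(tab, "facility_kind") <- facility_kind
  attr(tab, "metric") <- metric
  attr(tab, "scenario") <- scenario
  class(tab) <- c("accessibility_table", "data.frame")
  tab
}

#' @export
print.accessibility_table <- function(x, ...) {
  cat(sprintf("<accessibility_table> %s / %s / %s\n",
              attr(x, "facility_kind"), attr(x, "metric"),
              attr(x, "scenario")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Sites with poor access to both facility kinds
#'
#' A site is dually vulnerable when its travel time exceeds `threshold_min`
#' to the nearest PHC AND to the nearest CHS (strictly greater). The
#' scenario the times were computed under must be stated and is recorded
#' on the result.
#'
#' @param times data frame with `origin_id` (or `site_id`), `time_phc_min`,
#'   `time_chs_min`.
#' @param threshold_min vulnerability threshold (60 min = the conventional
#'   1 h poor-access cutoff).
#' @param scenario `"dry"` or `"rain"` (metadata, required).
#' @return subset of `times` rows that are vulnerable, with attribute
#'   `scenario` and `threshold_min`.
#' @export
vulnerable_sites <- function(times, threshold_min = 60,
                             scenario = c("dry", "rain")) {
  scenario <- match.arg(scenario)
  if (!all(c("time_phc_min", "time_chs_min") %in% names(times))) {
    wa_stop("`times` needs both `time_phc_min` and `time_chs_min`")
  }
  if (anyNA(times$time_phc_min) || anyNA(times$time_chs_min)) {
    wa_stop("missing travel time for one facility kind")
  }
  out <- times[times$time_phc_min > threshold_min &
               times$time_chs_min > threshold_min, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scenario") <- scenario
  attr(out, "threshold_min") <- threshold_min
  out
}

#' Inverse-distance-weighted interpolation surface
#'
#' Visualisation-only smoother of per-site values over a grid: each cell
#' takes the IDW mean of its `k_neighbors` nearest sites with weights
#' `1 / d^power`; a cell coinciding with a site takes that site's value
#' exactly. Values are convex combinations, so the surface is bounded by
#' the input range.
#'
#' @param sites data frame with `x`, `y`.
#' @param values one value per site.
#' @param grid template `spatial_grid` (geometry reused).
#' @param power IDW exponent.
#' @param k_neighbors number of neighbours.
#' @return a `terrain_grid`-like `spatial_grid` of interpolated values.
#' @export
idw_surface <- function(sites, values, grid, power = 2, k_neighbors = 12) {
  if (nrow(sites) < 1L) wa_stop("need at least one site")
  if (length(values) != nrow(sites)) wa_stop("one value per site required")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cx <- grid$origin[1] + (seq_len(nc) - 0.5) * grid$cell_size
  cy <- grid$origin[2] + (seq_len(nr) - 0.5) * grid$cell_size
  k <- min(k_neighbors, nrow(sites))
  out <- matrix(NA_real_, nr, nc)
  sx <- sites$x; sy <- sites$y
  for (r in seq_len(nr)) {
    d2 <- outer(rep(cy[r], nc), sy, function(a, b) (a - b)^2) +
      outer(cx, sx, function(a, b) (a - b)^2)
    for (cc in seq_len(nc)) {
      dd <- d2[cc, ]
      nb <- order(dd)[seq_len(k)]
      dn <- sqrt(dd[nb])
      if (dn[1] < 1e-9) {
        out[r, cc] <- values[nb[1]]
      } else {
        w <- 1 / dn^power
        out[r, cc] <- sum(w * values[nb]) / sum(w)
      }
    }
  }
  spatial_grid(out, origin = grid$origin, cell_size = grid$cell_size)
}
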