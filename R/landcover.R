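# Synthetic land cover: sequential exact-count allocation driven by smooth
# random score fields. Each class receives exactly its target number of
# cells (up to rounding), which keeps realized fractions tight while the
# smooth scores keep patches contiguous. Water and rice fields are biased
# to valley floors; residential cells hug the building clusters.

#' Generate a synthetic land-cover grid
#'
#' @param cfg a [district_config()].
#' @param terrain matching `terrain_grid` (same grid geometry).
#' @param sites optional [generate_sites()] output; when given, residential
#'   cells are allocated around its cluster centres, otherwise cluster
#'   centres are re-derived from `cfg$seed`.
#' @return a `landcover_grid` whose integer values index [lc_classes].
#' @export
generate_landcover <- function(cfg, terrain, sites = NULL) {
  if (!inherits(cfg, "district_config")) wa_stop("`cfg` must be a district_config")
  if (!inherits(terrain, "terrain_grid")) wa_stop("`terrain` must be a terrain_grid")
  n <- cfg$grid_size
  if (nrow(terrain$values) != n || ncol(terrain$values) != n) {
    wa_stop("`terrain` grid does not match cfg$grid_size")
  }
  centers <- if (!is.null(sites)) attr(sites, "cluster_centers") else
    attr(generate_sites(cfg, terrain), "cluster_centers")

  frac <- cfg$landcover_fractions
  ncell <- n * n
  targets <- floor(frac * ncell)
  # distribute rounding remainder to the largest classes
  short <- ncell - sum(targets)
  if (short > 0) {
    ord <- order(frac, decreasing = TRUE)
    targets[ord[seq_len(short)]] <- targets[ord[seq_len(short)]] + 1
  }

  with_seed(cfg$seed + 303L, {
    elev <- terrain$values
    relief <- max(diff(range(elev)), 1)
    noise <- function() gaussian_smooth(matrix(stats::rnorm(ncell), n, n),
                                        sigma = max(2, n / 30))
    # cell-centre coordinates
    cx <- (seq_len(n) - 0.5) * cfg$cell_size
    xs <- matrix(cx, n, n, byrow = TRUE)  # columns vary with x
    ys <- matrix(cx, n, n)                # rows vary with y
    dmin <- matrix(Inf, n, n)
    for (k in seq_len(nrow(centers))) {
      dmin <- pmin(dmin, (xs - centers[k, 1])^2 + (ys - centers[k, 2])^2)
    }
    dmin <- sqrt(dmin)

    code <- matrix(NA_integer_, n, n)
    take <- function(score, class_name) {
      free <- which(is.na(code))
      m <- targets[[class_name]]
      if (m > 0) {
        sel <- free[order(score[free])[seq_len(min(m, length(free)))]]
        code[sel] <<- match(class_name, lc_classes)
      }
    }
    nz <- function() { z <- noise(); z / stats::sd(z) } # unit-scale smooth noise
    take(dmin / stats::sd(dmin) + 0.1 * nz(), "residential")
    take(elev / relief + 0.25 * nz(), "water")
    take(elev / relief + 0.35 * nz(), "rice_field")
    take(nz(), "forest")
    take(nz(), "other")
    code[is.na(code)] <- match("savanna", lc_classes)
    spatial_grid(code, origin = terrain$origin, cell_size = terrain$cell_size,
                 classes = lc_classes)
  })
}

#' Realized areal fraction per land-cover class
#' @param landcover a `landcover_grid`.
#' @return named numeric over [lc_classes].
#' @export
landcover_fractions_realized <- function(landcover) {
  tab <- tabulate(landcover$values, nbins = length(lc_classes))
  stats::setNames(tab / sum(tab), lc_classes)
}
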