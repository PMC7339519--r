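# Buildings and facilities. Residential clusters are placed by inhibition
# sampling (minimum-separation rejection), buildings scatter around their
# cluster centre, and facilities sit at cluster centres chosen to be
# mutually far apart (facilities serve villages, and spreading them mirrors
# sparse rural coverage).

#' Generate buildings and health facilities for a synthetic district
#'
#' @param cfg a [district_config()].
#' @param terrain matching `terrain_grid` (unused beyond extent checks, kept
#'   for signature symmetry with the other generators).
#' @return a `site_set` data frame with columns `id`, `x`, `y`, `kind`
#'   (`building`, `PHC`, `CHS`), `population_weight` and `cluster`. Cluster
#'   centres are attached as attribute `cluster_centers`.
#' @export
generate_sites <- function(cfg, terrain = NULL) {
  if (!inherits(cfg, "district_config")) wa_stop("`cfg` must be a district_config")
  side <- cfg$grid_size * cfg$cell_size
  with_seed(cfg$seed + 202L, {
    centers <- inhibition_sample(cfg$n_clusters, side,
                                 margin = 0.05 * side,
                                 min_sep = 0.55 * side / sqrt(cfg$n_clusters))
    # buildings: every cluster has the >= 4 buildings that define a
    # residential area; counts are 4 + Poisson(mean - 4)
    extra <- stats::rpois(cfg$n_clusters, max(cfg$buildings_per_cluster - 4, 0))
    counts <- 4L + extra
    radius <- max(3 * cfg$cell_size, 100)
    bx <- by <- bcl <- vector("list", cfg$n_clusters)
    for (k in seq_len(cfg$n_clusters)) {
      px <- centers[k, 1] + stats::rnorm(counts[k], sd = radius)
      py <- centers[k, 2] + stats::rnorm(counts[k], sd = radius)
      bx[[k]] <- pmin(pmax(px, 1), side - 1)
      by[[k]] <- pmin(pmax(py, 1), side - 1)
      bcl[[k]] <- rep(k, counts[k])
    }
    nb <- sum(counts)
    buildings <- data.frame(
      id = sprintf("b%04d", seq_len(nb)),
      x = unlist(bx), y = unlist(by),
      kind = "building", population_weight = 1,
      cluster = unlist(bcl), stringsAsFactors = FALSE
    )
    # facilities at cluster centres: PHCs first (greedy max-min spread),
    # then CHSs among the remaining clusters
    phc_idx <- greedy_spread(centers, cfg$n_phc)
    rest <- setdiff(seq_len(cfg$n_clusters), phc_idx)
    chs_idx <- rest[greedy_spread(centers[rest, , drop = FALSE],
                                  min(cfg$n_chs, length(rest)))]
    fac <- data.frame(
      id = c(sprintf("phc%02d", seq_along(phc_idx)),
             sprintf("chs%02d", seq_along(chs_idx))),
      x = centers[c(phc_idx, chs_idx), 1],
      y = centers[c(phc_idx, chs_idx), 2],
      kind = rep(c("PHC", "CHS"), c(length(phc_idx), length(chs_idx))),
      population_weight = 0,
      cluster = c(phc_idx, chs_idx), stringsAsFactors = FALSE
    )
    sites <- rbind(buildings, fac)
    rownames(sites) <- NULL
    attr(sites, "cluster_centers") <- centers
    class(sites) <- c("site_set", "data.frame")
    sites
  })
}

# n points in [margin, side - margin]^2 with pairwise separation >= min_sep
# (separation relaxed geometrically if the square is too crowded)
inhibition_sample <- function(n, side, margin, min_sep) {
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  sep <- min_sep
  tries <- 0L
  while (got < n) {
    cand <- stats::runif(2, margin, side - margin)
    ok <- got == 0L ||
      min(sqrt((pts[seq_len(got), 1] - cand[1])^2 +
               (pts[seq_len(got), 2] - cand[2])^2)) >= sep
    if (ok) {
      got <- got + 1L
      pts[got, ] <- cand
    }
    tries <- tries + 1L
    if (tries %% 2000L == 0L) sep <- sep * 0.8 # relax if crowded
  }
  pts
}

# greedy max-min selection of k row indices of a coordinate matrix
greedy_spread <- function(pts, k) {
  n <- nrow(pts)
  if (k >= n) return(seq_len(n))
  chosen <- which.min((pts[, 1] - mean(pts[, 1]))^2 +
                      (pts[, 2] - mean(pts[, 2]))^2)
  while (length(chosen) < k) {
    d <- rep(Inf, n)
    for (c in chosen) {
      d <- pmin(d, (pts[, 1] - pts[c, 1])^2 + (pts[, 2] - pts[c, 2])^2)
    }
    d[chosen] <- -Inf
    chosen <- c(chosen, which.max(d))
  }
  chosen
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("<site_set> %d buildings, %d PHC, %d CHS\n",
              sum(x$kind == "building"), sum(x$kind == "PHC"),
              sum(x$kind == "CHS")))
  invisible(x)
}
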