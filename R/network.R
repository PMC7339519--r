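# The footpath network: an undirected graph whose nodes are junctions
# (cluster centres and facilities) and whose edges carry full polyline
# geometry plus arc length. This is the routing substrate; everything
# downstream measures distance along these polylines, never as the crow
# flies.

#' Construct a path network
#'
#' @param nodes data frame with columns `id` (integer), `x`, `y`.
#' @param edges data frame with columns `id`, `from`, `to` (node ids).
#' @param geoms list of polylines (n x 2 matrices), one per edge, in edge
#'   `id` order; each polyline must start at `from` and end at `to`.
#' @return a `path_network`.
#' @export
path_network <- function(nodes, edges, geoms) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (anyDuplicated(nodes$id)) wa_stop("duplicate node ids")
  if (nrow(edges) != length(geoms)) wa_stop("one geometry per edge required")
  lens <- vapply(geoms, polyline_length, numeric(1))
  if (any(lens <= 0)) wa_stop("zero-length edges are not allowed")
  # geometry endpoints must coincide with node coordinates
  for (i in seq_len(nrow(edges))) {
    a <- nodes[match(edges$from[i], nodes$id), c("x", "y")]
    b <- nodes[match(edges$to[i], nodes$id), c("x", "y")]
    g <- geoms[[i]]
    if (euclidean_dist(as.numeric(a), g[1, ]) > 1e-6 ||
        euclidean_dist(as.numeric(b), g[nrow(g), ]) > 1e-6) {
      wa_stop("edge ", edges$id[i], " geometry does not join its nodes")
    }
  }
  edges$length <- lens
  net <- list(nodes = nodes, edges = edges, geoms = geoms)
  class(net) <- "path_network"
  net
}

#' @export
print.path_network <- function(x, ...) {
  cat(sprintf("<path_network> %d nodes, %d edges, %.1f km total\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length) / 1000))
  invisible(x)
}

# igraph view of the junction graph (edge weights = polyline lengths)
network_graph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$from),
               to = as.character(net$edges$to),
               weight = net$edges$length,
               edge_id = net$edges$id),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id))
  )
}

#' Is the network a single connected component?
#' @export
network_is_connected <- function(net) {
  igraph::is_connected(network_graph(net))
}

#' Generate a connected footpath network over the district
#'
#' Junctions are the residential cluster centres and facilities. The edge
#' set is a Euclidean minimum spanning tree (guaranteeing connectivity)
#' augmented with k-nearest-neighbour links, which yields the loopy but
#' sparse path webs typical of rural footpath maps. Each edge's geometry is
#' a jittered polyline, so footpaths bend and edge length exceeds the
#' straight-line separation.
#'
#' @param cfg a [district_config()].
#' @param terrain matching `terrain_grid`.
#' @param sites [generate_sites()] output.
#' @param k neighbours per node for the augmentation pass.
#' @return a `path_network`.
#' @export
generate_network <- function(cfg, terrain, sites, k = 3) {
  if (!inherits(sites, "site_set")) wa_stop("`sites` must be a site_set")
  # facilities sit at cluster centres, so the unique centres are the junctions
  centers <- attr(sites, "cluster_centers")
  pts <- unique(round(centers, 9))
  n <- nrow(pts)
  if (n < 2) wa_stop("need at least two junctions to build a network")
  with_seed(cfg$seed + 404L, {
    d <- as.matrix(stats::dist(pts))
    # MST via igraph for connectivity
    g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                  weighted = TRUE)
    mst <- igraph::mst(g_full)
    el <- igraph::as_edgelist(mst, names = FALSE)
    # augment with k nearest neighbours
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:min(k + 1, n)]
      el <- rbind(el, cbind(i, nb))
    }
    el <- t(apply(el, 1, sort))
    el <- unique(el)
    nodes <- data.frame(id = seq_len(n), x = pts[, 1], y = pts[, 2])
    geoms <- vector("list", nrow(el))
    side <- cfg$grid_size * cfg$cell_size
    for (e in seq_len(nrow(el))) {
      geoms[[e]] <- jitter_polyline(pts[el[e, 1], ], pts[el[e, 2], ],
                                    side = side)
    }
    edges <- data.frame(id = seq_len(nrow(el)), from = el[, 1], to = el[, 2])
    net <- path_network(nodes, edges, geoms)
    if (!network_is_connected(net)) {
      wa_stop("internal error: generated network is disconnected")
    }
    net
  })
}

# bent footpath between two junctions: subdivide the straight connector and
# jitter interior vertices perpendicular to it
jitter_polyline <- function(a, b, side, spacing = 200, rel_jitter = 0.12) {
  len <- euclidean_dist(a, b)
  nseg <- max(2L, ceiling(len / spacing))
  t <- seq(0, 1, length.out = nseg + 1L)
  px <- a[1] + t * (b[1] - a[1])
  py <- a[2] + t * (b[2] - a[2])
  # unit normal
  nx <- -(b[2] - a[2]) / len
  ny <- (b[1] - a[1]) / len
  amp <- rel_jitter * len / nseg
  off <- c(0, stats::rnorm(nseg - 1L, sd = amp), 0)
  px <- pmin(pmax(px + off * nx, 0), side)
  py <- pmin(pmax(py + off * ny, 0), side)
  as_polyline(cbind(px, py))
}

#' Snap a site to the nearest point on the network
#'
#' Scans every edge polyline and returns the globally nearest point; exact
#' ties are broken by the lowest edge id so snapping is deterministic.
#'
#' @param site list/row with `x`, `y` (a `site_set` row works).
#' @param network a `path_network`.
#' @return list with `edge_id`, `offset_m` (arc length from the edge's
#'   `from` node), `snap_point`, `snap_dist`.
#' @export
snap_site <- function(site, network) {
  if (!inherits(network, "path_network")) wa_stop("`network` must be a path_network")
  if (nrow(network$edges) == 0L) wa_stop("cannot snap to an empty network")
  p <- c(as.numeric(site$x), as.numeric(site$y))
  best <- NULL
  ord <- order(network$edges$id)
  for (i in ord) {
    pr <- project_point(network$geoms[[i]], p)
    if (is.null(best) || pr$dist < best$snap_dist - 1e-12) {
      best <- list(edge_id = network$edges$id[i], offset_m = pr$station,
                   snap_point = pr$point, snap_dist = pr$dist)
    }
  }
  best
}
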