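# Shortest-path routing over the footpath network. Sites are snapped onto
# edge polylines; the search itself is Dijkstra on the junction graph with
# the four origin/destination edge-end combinations (plus the direct
# along-edge path when both sites snap to the same edge) compared
# explicitly, so snapped mid-edge positions are handled without mutating
# the graph.

#' Shortest route between two sites
#'
#' @param origin_site,dest_site rows/lists with `x`, `y` and optionally `id`.
#' @param network a `path_network`.
#' @return a `route`: list with `origin_id`, `dest_id`, `node_seq`,
#'   `polyline`, `length_m`. Errors if no path exists.
#' @export
shortest_route <- function(origin_site, dest_site, network) {
  s1 <- snap_site(origin_site, network)
  s2 <- snap_site(dest_site, network)
  g <- network_graph(network)
  r <- route_between_snaps(s1, s2, network, g)
  if (!is.finite(r$length_m)) {
    wa_stop("no route between ", site_id(origin_site), " and ",
            site_id(dest_site), ": network disconnected between snap points")
  }
  r$origin_id <- site_id(origin_site)
  r$dest_id <- site_id(dest_site)
  r
}

site_id <- function(site) {
  if (!is.null(site$id)) as.character(site$id) else "<site>"
}

# core: route between two snap results. D, if given, is the full junction
# distance matrix (dimnames = node ids) used to shortcut the search.
route_between_snaps <- function(s1, s2, network, g, D = NULL) {
  e1 <- which(network$edges$id == s1$edge_id)
  e2 <- which(network$edges$id == s2$edge_id)
  g1 <- network$geoms[[e1]]; g2 <- network$geoms[[e2]]
  L1 <- network$edges$length[e1]; L2 <- network$edges$length[e2]
  ends1 <- data.frame(node = c(network$edges$from[e1], network$edges$to[e1]),
                      cost = c(s1$offset_m, L1 - s1$offset_m))
  ends2 <- data.frame(node = c(network$edges$from[e2], network$edges$to[e2]),
                      cost = c(s2$offset_m, L2 - s2$offset_m))

  # candidate 0: both on the same edge, walk along it
  best <- NULL
  if (e1 == e2) {
    best <- list(kind = "direct", cost = abs(s2$offset_m - s1$offset_m))
  }
  # candidates via junctions
  if (is.null(D)) {
    D <- igraph::distances(g, v = as.character(unique(ends1$node)),
                           to = as.character(unique(ends2$node)))
  }
  for (i in 1:2) {
    for (j in 1:2) {
      mid <- D[as.character(ends1$node[i]), as.character(ends2$node[j])]
      cost <- ends1$cost[i] + mid + ends2$cost[j]
      if (is.null(best) || cost < best$cost - 1e-9) {
        best <- list(kind = "via", cost = cost, i = i, j = j)
      }
    }
  }
  if (!is.finite(best$cost)) {
    return(structure(list(origin_id = NA, dest_id = NA, node_seq = integer(),
                          polyline = NULL, length_m = Inf), class = "route"))
  }

  if (best$kind == "direct") {
    piece <- sub_polyline(g1, min(s1$offset_m, s2$offset_m),
                          max(s1$offset_m, s2$offset_m))
    if (s1$offset_m > s2$offset_m) piece <- rev_polyline(piece)
    if (best$cost == 0) piece <- as_polyline(rbind(s1$snap_point, s2$snap_point))
    return(structure(list(origin_id = NA, dest_id = NA, node_seq = integer(),
                          polyline = piece, length_m = polyline_length(piece)),
                     class = "route"))
  }

  from_node <- ends1$node[best$i]
  to_node <- ends2$node[best$j]
  sp <- igraph::shortest_paths(g, from = as.character(from_node),
                               to = as.character(to_node), output = "both")
  vpath <- as.integer(igraph::as_ids(sp$vpath[[1]]))
  epath <- sp$epath[[1]]
  # origin piece: snap point -> chosen end of edge e1
  p_start <- if (best$i == 1) rev_polyline(sub_polyline(g1, 0, s1$offset_m))
             else sub_polyline(g1, s1$offset_m, L1)
  # middle: full edges oriented along vpath
  mid_ids <- if (length(epath)) igraph::edge_attr(g, "edge_id", epath) else integer()
  pieces <- list(p_start)
  for (k in seq_along(mid_ids)) {
    ei <- which(network$edges$id == mid_ids[k])
    ge <- network$geoms[[ei]]
    if (network$edges$from[ei] != vpath[k]) ge <- rev_polyline(ge)
    pieces[[length(pieces) + 1L]] <- ge
  }
  p_end <- if (best$j == 1) sub_polyline(g2, 0, s2$offset_m)
           else rev_polyline(sub_polyline(g2, s2$offset_m, L2))
  pieces[[length(pieces) + 1L]] <- p_end
  poly <- do.call(rbind, pieces)
  # drop consecutive duplicate vertices introduced at joints
  keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-9)
  poly <- as_polyline(poly[keep, , drop = FALSE])
  if (nrow(poly) < 2L) poly <- as_polyline(rbind(poly[1, ], poly[1, ]))
  structure(list(origin_id = NA, dest_id = NA, node_seq = vpath,
                 polyline = poly, length_m = polyline_length(poly)),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  cat(sprintf("<route> %s -> %s, %.1f m, %d junctions\n",
              x$origin_id, x$dest_id, x$length_m, length(x$node_seq)))
  invisible(x)
}

#' Route every building to its nearest facility of a kind
#'
#' Nearest is by network distance (not Euclidean, not time). The search
#' runs one Dijkstra per facility over the junction graph; ties between
#' equidistant facilities are broken by the lowest facility id. Buildings
#' disconnected from every facility come back with `length_m = Inf` and a
#' `NULL` polyline rather than being dropped.
#'
#' @param buildings,facilities `site_set` subsets (facilities are filtered
#'   by `facility_kind`).
#' @param network a `path_network`.
#' @param facility_kind `"PHC"` or `"CHS"`.
#' @return list of `route` objects (one per building, in building order),
#'   each with `facility_id` and `facility_kind` fields set.
#' @export
nearest_facility_routes <- function(buildings, facilities, network,
                                    facility_kind = c("PHC", "CHS")) {
  facility_kind <- match.arg(facility_kind)
  fac <- facilities[facilities$kind == facility_kind, , drop = FALSE]
  if (nrow(fac) == 0L) wa_stop("no facility of kind ", facility_kind)
  fac <- fac[order(fac$id), , drop = FALSE] # tie-break order
  g <- network_graph(network)
  D <- igraph::distances(g)
  rownames(D) <- colnames(D) <- igraph::V(g)$name

  bsnap <- lapply(seq_len(nrow(buildings)), function(i)
    snap_site(buildings[i, ], network))
  fsnap <- lapply(seq_len(nrow(fac)), function(i) snap_site(fac[i, ], network))

  out <- vector("list", nrow(buildings))
  for (b in seq_len(nrow(buildings))) {
    best_f <- NA_integer_
    best_d <- Inf
    for (f in seq_len(nrow(fac))) {
      d <- snap_pair_distance(bsnap[[b]], fsnap[[f]], network, D)
      if (d < best_d - 1e-9) {
        best_d <- d
        best_f <- f
      }
    }
    if (!is.finite(best_d)) {
      out[[b]] <- structure(list(origin_id = buildings$id[b], dest_id = NA,
                                 node_seq = integer(), polyline = NULL,
                                 length_m = Inf,
                                 facility_id = NA_character_,
                                 facility_kind = facility_kind),
                            class = "route")
      next
    }
    r <- route_between_snaps(bsnap[[b]], fsnap[[best_f]], network, g, D = D)
    r$origin_id <- buildings$id[b]
    r$dest_id <- fac$id[best_f]
    r$facility_id <- fac$id[best_f]
    r$facility_kind <- facility_kind
    out[[b]] <- r
  }
  out
}

# network distance between two snap results using a precomputed junction
# distance matrix
snap_pair_distance <- function(s1, s2, network, D) {
  e1 <- which(network$edges$id == s1$edge_id)
  e2 <- which(network$edges$id == s2$edge_id)
  L1 <- network$edges$length[e1]; L2 <- network$edges$length[e2]
  n1 <- c(network$edges$from[e1], network$edges$to[e1])
  c1 <- c(s1$offset_m, L1 - s1$offset_m)
  n2 <- c(network$edges$from[e2], network$edges$to[e2])
  c2 <- c(s2$offset_m, L2 - s2$offset_m)
  d <- Inf
  if (e1 == e2) d <- abs(s1$offset_m - s2$offset_m)
  for (i in 1:2) {
    for (j in 1:2) {
      d <- min(d, c1[i] + D[as.character(n1[i]), as.character(n2[j])] + c2[j])
    }
  }
  d
}

#' Distance summary for nearest-facility routes
#'
#' @param routes output of [nearest_facility_routes()].
#' @return data frame `building_id`, `facility_kind`, `facility_id`,
#'   `distance_m`.
#' @export
routes_distance_table <- function(routes) {
  data.frame(
    building_id = vapply(routes, function(r) as.character(r$origin_id), ""),
    facility_kind = vapply(routes, function(r) as.character(r$facility_kind), ""),
    facility_id = vapply(routes, function(r) as.character(r$facility_id), ""),
    distance_m = vapply(routes, function(r) r$length_m, numeric(1)),
    stringsAsFactors = FALSE
  )
}
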