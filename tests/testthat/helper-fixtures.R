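# Fixtures and independent oracles shared across the suite. Everything is
# built in code; nothing is read from disk.

# --- grids ----------------------------------------------------------------

flat_terrain <- function(n = 40, cell = 25, elev = 300, origin = c(0, 0)) {
  spatial_grid(matrix(elev, n, n), origin = origin, cell_size = cell)
}

# planar ramp climbing `grade` percent toward +x (bilinear-exact)
ramp_terrain <- function(n = 40, cell = 25, grade = 10, origin = c(0, 0)) {
  xs <- origin[1] + (seq_len(n) - 0.5) * cell
  spatial_grid(matrix(xs * grade / 100, n, n, byrow = TRUE),
               origin = origin, cell_size = cell)
}

uniform_landcover <- function(class = "savanna", n = 40, cell = 25,
                              origin = c(0, 0)) {
  spatial_grid(matrix(match(class, lc_classes), n, n), origin = origin,
               cell_size = cell, classes = lc_classes)
}

# columns cycle water/forest/rice_field so every 100 m segment is "mixed"
cycling_landcover <- function(n = 40, cell = 25, origin = c(0, 0)) {
  codes <- match(c("water", "forest", "rice_field"), lc_classes)
  m <- matrix(rep(codes, length.out = n), n, n, byrow = TRUE)
  spatial_grid(m, origin = origin, cell_size = cell, classes = lc_classes)
}

# --- networks -------------------------------------------------------------

# build a network from a node data frame and an edge list of node-id pairs,
# with straight-line geometries
make_network <- function(nodes, edge_pairs) {
  geoms <- lapply(seq_len(nrow(edge_pairs)), function(i) {
    a <- as.numeric(nodes[match(edge_pairs[i, 1], nodes$id), c("x", "y")])
    b <- as.numeric(nodes[match(edge_pairs[i, 2], nodes$id), c("x", "y")])
    rbind(a, b)
  })
  path_network(nodes,
               data.frame(id = seq_len(nrow(edge_pairs)),
                          from = edge_pairs[, 1], to = edge_pairs[, 2]),
               geoms)
}

# random connected network on n nodes (MST + extra random edges)
random_network <- function(n_nodes, extra = 3, side = 2000) {
  pts <- matrix(stats::runif(2 * n_nodes, 0, side), n_nodes, 2)
  d <- as.matrix(stats::dist(pts))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  el <- igraph::as_edgelist(igraph::mst(g), names = FALSE)
  if (extra > 0) {
    for (k in seq_len(extra)) {
      ij <- sample.int(n_nodes, 2)
      el <- rbind(el, sort(ij))
    }
  }
  el <- unique(t(apply(el, 1, sort)))
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  make_network(data.frame(id = seq_len(n_nodes), x = pts[, 1], y = pts[, 2]),
               el)
}

# exhaustive-enumeration shortest path length between two NODES (oracle,
# independent of igraph): depth-first over all simple paths
enumerate_shortest <- function(net, from, to) {
  best <- Inf
  edges <- net$edges
  recurse <- function(node, visited, acc) {
    if (acc >= best) return()
    if (node == to) {
      best <<- acc
      return()
    }
    inc <- which(edges$from == node | edges$to == node)
    for (e in inc) {
      nxt <- if (edges$from[e] == node) edges$to[e] else edges$from[e]
      if (nxt %in% visited) next
      recurse(nxt, c(visited, nxt), acc + edges$length[e])
    }
  }
  recurse(from, from, 0)
  best
}

# --- small district cache -------------------------------------------------

.fixture_env <- new.env(parent = emptyenv())

# small but fully featured district for oracle tests
mini_district <- function() {
  if (is.null(.fixture_env$mini)) {
    cfg <- district_config(grid_size = 100, cell_size = 25, n_clusters = 10,
                           n_phc = 2, n_chs = 3, terrain_relief = 120,
                           seed = 7L)
    terrain <- generate_terrain(cfg)
    sites <- generate_sites(cfg, terrain)
    landcover <- generate_landcover(cfg, terrain, sites)
    network <- generate_network(cfg, terrain, sites)
    .fixture_env$mini <- list(cfg = cfg, terrain = terrain, sites = sites,
                              landcover = landcover, network = network)
  }
  .fixture_env$mini
}

# full-size default district (shared by paper-scale tests)
default_district <- function() {
  if (is.null(.fixture_env$full)) {
    cfg <- district_config(seed = 1L)
    terrain <- generate_terrain(cfg)
    sites <- generate_sites(cfg, terrain)
    landcover <- generate_landcover(cfg, terrain, sites)
    network <- generate_network(cfg, terrain, sites)
    .fixture_env$full <- list(cfg = cfg, terrain = terrain, sites = sites,
                              landcover = landcover, network = network)
  }
  .fixture_env$full
}

# a couple of nearest-facility routes on the mini district
mini_routes <- function(kind = "PHC", n = 10) {
  d <- mini_district()
  b <- d$sites[d$sites$kind == "building", ][seq_len(n), ]
  f <- d$sites[d$sites$kind != "building", ]
  nearest_facility_routes(b, f, d$network, kind)
}

# noiseless copy of a model
noiseless <- function(model) {
  model$sigma_b <- 0
  model$sigma_eps <- 0
  model
}
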