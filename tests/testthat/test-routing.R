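# Routing: snapping, Dijkstra vs exhaustive enumeration, nearest-facility
# search, and the metric invariants of a footpath network.

test_that("snap_site: on-node snap, deterministic tie-break, brute force", {
  # V-shaped network: two edges meeting at the origin
  net <- make_network(data.frame(id = 1:3, x = c(0, 100, 0), y = c(0, 0, 100)),
                      rbind(c(1, 2), c(1, 3)))
  on_node <- snap_site(list(x = 100, y = 0), net)
  expect_equal(on_node$snap_dist, 0)
  expect_equal(on_node$edge_id, 1)
  expect_equal(on_node$offset_m, 100)
  # equidistant from both edges -> lowest edge id wins
  tie <- snap_site(list(x = 50, y = 50), net)
  expect_equal(tie$edge_id, 1)
  expect_equal(tie$snap_dist, 50)
  expect_error(snap_site(list(x = 0, y = 0),
                         structure(list(nodes = data.frame(), edges = data.frame(),
                                        geoms = list()),
                                   class = "path_network")),
               "empty")
})

test_that("snap_site agrees with a dense-sampling oracle", {
  set.seed(42)
  net <- random_network(8, extra = 2)
  for (k in 1:10) {
    p <- list(x = runif(1, 0, 2000), y = runif(1, 0, 2000))
    got <- snap_site(p, net)
    # oracle: sample every edge densely, take the global minimum
    best_d <- Inf; best_edge <- NA
    for (i in seq_len(nrow(net$edges))) {
      ge <- net$geoms[[i]]
      st <- seq(0, net$edges$length[i], by = 0.05)
      for (s in st) {
        q <- ge[1, ] + s / net$edges$length[i] * (ge[2, ] - ge[1, ])
        dd <- sqrt((q[1] - p$x)^2 + (q[2] - p$y)^2)
        if (dd < best_d) { best_d <- dd; best_edge <- net$edges$id[i] }
      }
    }
    expect_lt(abs(got$snap_dist - best_d), 0.05)
    expect_equal(got$edge_id, best_edge)
  }
})

test_that("shortest_route takes the direct 5-edge of a 3-4-5 triangle", {
  net <- make_network(data.frame(id = 1:3, x = c(0, 4, 0), y = c(0, 0, 3)),
                      rbind(c(1, 2), c(1, 3), c(2, 3)))
  r <- shortest_route(list(id = "o", x = 4, y = 0), list(id = "d", x = 0, y = 3),
                      net)
  expect_equal(r$length_m, 5, tolerance = 1e-12)
  # and the polyline really is the hypotenuse
  expect_equal(nrow(r$polyline), 2)
})

test_that("origin equal to destination yields a zero-length route", {
  net <- make_network(data.frame(id = 1:2, x = c(0, 100), y = c(0, 0)),
                      cbind(1, 2))
  r <- shortest_route(list(id = "a", x = 30, y = 5), list(id = "a", x = 30, y = 5),
                      net)
  expect_equal(r$length_m, 0)
})

test_that("Dijkstra equals exhaustive enumeration on random small graphs", {
  set.seed(7)
  for (k in 1:30) {
    n <- sample(4:10, 1)
    net <- random_network(n, extra = sample(1:4, 1))
    ab <- sample.int(n, 2)
    a <- net$nodes[net$nodes$id == ab[1], ]
    b <- net$nodes[net$nodes$id == ab[2], ]
    r <- shortest_route(list(id = "a", x = a$x, y = a$y),
                        list(id = "b", x = b$x, y = b$y), net)
    oracle <- enumerate_shortest(net, ab[1], ab[2])
    expect_equal(r$length_m, oracle, tolerance = 1e-9)
  }
})

test_that("route length is symmetric in origin and destination", {
  d <- mini_district()
  b <- d$sites[d$sites$kind == "building", ]
  set.seed(3)
  for (k in 1:5) {
    ij <- sample.int(nrow(b), 2)
    r1 <- shortest_route(b[ij[1], ], b[ij[2], ], d$network)
    r2 <- shortest_route(b[ij[2], ], b[ij[1], ], d$network)
    expect_equal(r1$length_m, r2$length_m, tolerance = 1e-9)
  }
})

test_that("adding an edge never increases a shortest distance", {
  set.seed(11)
  net <- random_network(7, extra = 0) # a tree
  pairs <- rbind(c(1, 5), c(2, 7), c(3, 6))
  before <- apply(pairs, 1, function(p) {
    a <- net$nodes[p[1], ]; b <- net$nodes[p[2], ]
    shortest_route(list(id = 1, x = a$x, y = a$y),
                   list(id = 2, x = b$x, y = b$y), net)$length_m
  })
  # add a shortcut edge between nodes 1 and 7
  aug_edges <- rbind(cbind(net$edges$from, net$edges$to), c(1, 7))
  net2 <- make_network(net$nodes, aug_edges)
  after <- apply(pairs, 1, function(p) {
    a <- net2$nodes[p[1], ]; b <- net2$nodes[p[2], ]
    shortest_route(list(id = 1, x = a$x, y = a$y),
                   list(id = 2, x = b$x, y = b$y), net2)$length_m
  })
  expect_true(all(after <= before + 1e-9))
})

test_that("nearest facility is by network distance, not Euclidean", {
  # U-shaped single path; facility A is Euclid-near the building but
  # network-far, facility B sits midway along the building's own leg
  u_poly <- rbind(c(0, 0), c(1000, 0), c(1000, 10), c(0, 10))
  net <- path_network(data.frame(id = 1:2, x = c(0, 0), y = c(0, 10)),
                      data.frame(id = 1, from = 1, to = 2),
                      list(u_poly))
  b <- data.frame(id = "b1", x = 0, y = 0, kind = "building",
                  population_weight = 1)
  fac <- data.frame(id = c("phcA", "phcB"), x = c(0, 500), y = c(12, 0),
                    kind = "PHC", population_weight = 0)
  rr <- nearest_facility_routes(b, fac, net, "PHC")
  expect_equal(rr[[1]]$facility_id, "phcB")
  expect_equal(rr[[1]]$length_m, 500, tolerance = 1e-9)
})

test_that("single facility receives every route; brute force on 50 buildings", {
  d <- mini_district()
  b <- d$sites[d$sites$kind == "building", ][1:50, ]
  f <- d$sites[d$sites$kind != "building", ]
  phc <- f[f$kind == "PHC", ]
  one <- nearest_facility_routes(b, phc[1, ], d$network, "PHC")
  expect_true(all(vapply(one, function(r) r$facility_id, "") == phc$id[1]))

  rr <- nearest_facility_routes(b, f, d$network, "PHC")
  # oracle: route to each facility independently, take the minimum
  # (lowest facility id on ties)
  for (i in seq_len(nrow(b))) {
    per_fac <- vapply(seq_len(nrow(phc)), function(j)
      shortest_route(b[i, ], phc[j, ], d$network)$length_m, numeric(1))
    best <- order(per_fac, phc$id)[1]
    expect_equal(rr[[i]]$length_m, per_fac[best], tolerance = 1e-9)
    expect_equal(rr[[i]]$facility_id, phc$id[best])
  }
  # building order does not change per-building results
  rr_rev <- nearest_facility_routes(b[rev(seq_len(nrow(b))), ], f,
                                    d$network, "PHC")
  expect_equal(rr[[1]]$length_m, rr_rev[[50]]$length_m)
})

test_that("network distance dominates the straight line on every route", {
  rr <- mini_routes("PHC", n = 20)
  d <- mini_district()
  b <- d$sites[d$sites$kind == "building", ][1:20, ]
  f <- d$sites
  for (i in seq_along(rr)) {
    dest <- f[f$id == rr[[i]]$facility_id, ]
    straight <- sqrt((b$x[i] - dest$x)^2 + (b$y[i] - dest$y)^2)
    # snapping offsets can only shorten the walked part, never below the
    # chord between the snapped endpoints; compare against the polyline's
    # own endpoints to keep the inequality exact
    pl <- rr[[i]]$polyline
    chord <- sqrt(sum((pl[nrow(pl), ] - pl[1, ])^2))
    expect_gte(rr[[i]]$length_m + 1e-9, chord)
  }
})

test_that("route length always equals its polyline arc length", {
  rr <- mini_routes("CHS", n = 10)
  for (r in rr) {
    pl <- r$polyline
    arc <- sum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2))
    expect_equal(r$length_m, arc, tolerance = 1e-9)
  }
})
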