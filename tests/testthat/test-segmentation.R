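# Segmentation: polyline splitting, covariate attribution, pair speeds.

test_that("split_polyline: exact pieces and arc-length preservation", {
  line <- rbind(c(0, 10), c(250, 10))
  segs <- split_polyline(line)
  expect_equal(length(segs), 3)
  expect_equal(vapply(segs, function(s) s$end_m - s$start_m, numeric(1)),
               c(100, 100, 50))
  one <- split_polyline(rbind(c(0, 0), c(100, 0)))
  expect_equal(length(one), 1)
  expect_error(split_polyline(rbind(c(1, 1), c(1, 1))), "zero-length")

  set.seed(5)
  pl <- cbind(cumsum(runif(40, 5, 60)), cumsum(rnorm(40, 0, 15)))
  segs <- split_polyline(pl, 100)
  total <- sum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2))
  pieces <- vapply(segs, function(s)
    sum(sqrt(diff(s$polyline[, 1])^2 + diff(s$polyline[, 2])^2)), numeric(1))
  expect_equal(sum(pieces), total, tolerance = 1e-9)
  # pieces partition the parent: each starts where the previous ended
  for (i in 2:length(segs)) {
    expect_equal(segs[[i]]$polyline[1, ],
                 segs[[i - 1]]$polyline[nrow(segs[[i - 1]]$polyline), ],
                 tolerance = 1e-9)
  }
})

test_that("attribute_covariates: slope definition and flat limit", {
  lc <- uniform_landcover("forest", n = 40)
  flat <- flat_terrain(40)
  seg <- split_polyline(rbind(c(100, 500), c(300, 500)))[[1]]
  a <- attribute_covariates(seg, flat, lc, rainfall_mm = 12)
  expect_equal(a$slope_pct, 0)
  expect_equal(a$landcover_label, "forest")
  expect_equal(a$cumdist_category, "short")
  expect_equal(a$rainfall_mm, 12)

  ramp <- ramp_terrain(40, grade = 15) # +15 m per 100 m toward +x
  up <- attribute_covariates(seg, ramp, lc)
  expect_equal(up$slope_pct, 15, tolerance = 1e-9)
  # reversing the direction of travel negates the slope, keeps the label
  rseg <- seg
  rseg$polyline <- rseg$polyline[2:1, ]
  down <- attribute_covariates(rseg, ramp, lc)
  expect_equal(down$slope_pct, -15, tolerance = 1e-9)
  expect_equal(down$landcover_label, up$landcover_label)
  # idempotence
  expect_equal(attribute_covariates(a, flat, lc, rainfall_mm = 12), a)
  # outside the grids -> input error
  segs_far <- split_polyline(rbind(c(100, 500), c(5000, 500)))
  expect_error(attribute_covariates(segs_far[[length(segs_far)]], flat, lc),
               "outside")
})

test_that("mixed label kicks in below 50% predominance", {
  # x-banded cover: 45% water, 35% savanna, 20% forest along a 100 m run
  codes <- match(c(rep("water", 9), rep("savanna", 7), rep("forest", 4)),
                 lc_classes)
  lc <- spatial_grid(matrix(codes, 20, 20, byrow = TRUE),
                     cell_size = 5, classes = lc_classes)
  flat <- flat_terrain(20, cell = 5)
  seg <- split_polyline(rbind(c(0, 50), c(100, 50)))[[1]]
  a <- attribute_covariates(seg, flat, lc)
  expect_equal(a$landcover_label, "mixed")
  # a 55/45 split keeps the majority class
  codes2 <- match(c(rep("water", 11), rep("savanna", 9)), lc_classes)
  lc2 <- spatial_grid(matrix(codes2, 20, 20, byrow = TRUE),
                      cell_size = 5, classes = lc_classes)
  expect_equal(attribute_covariates(seg, flat, lc2)$landcover_label, "water")
})

test_that("a route inside one class never yields a mixed segment", {
  d <- mini_district()
  lc <- uniform_landcover("savanna", n = d$cfg$grid_size,
                          cell = d$cfg$cell_size)
  r <- mini_routes("PHC", 3)[[2]]
  segs <- segment_route(r$polyline, d$terrain, lc)
  expect_true(all(segs$landcover_label == "savanna"))
})

test_that("segment_route matches the one-segment-at-a-time path", {
  d <- mini_district()
  r <- mini_routes("PHC", 3)[[1]]
  fast <- segment_route(r$polyline, d$terrain, d$landcover, rainfall_mm = 7)
  slow <- split_polyline(r$polyline)
  for (i in seq_along(slow)) {
    s <- attribute_covariates(slow[[i]], d$terrain, d$landcover,
                              rainfall_mm = 7)
    expect_equal(fast$slope_pct[i], s$slope_pct, tolerance = 1e-9)
    expect_equal(fast$landcover_label[i], s$landcover_label)
    expect_equal(fast$cumdist_category[i], s$cumdist_category)
  }
})

test_that("cumulative-distance category switches past 13 km", {
  big <- flat_terrain(n = 40, cell = 500) # 20 km side
  lc <- uniform_landcover("savanna", n = 40, cell = 500)
  segs <- segment_route(rbind(c(100, 1000), c(14100, 1000)), big, lc)
  expect_equal(segs$cumdist_category[segs$start_m < 12900],
               rep("short", sum(segs$start_m < 12900)))
  expect_true(all(segs$cumdist_category[segs$start_m >= 13000] == "long"))
  # offset carries over for chained journeys
  segs2 <- segment_route(rbind(c(100, 1000), c(1100, 1000)), big, lc,
                         cumdist_offset_m = 13000)
  expect_true(all(segs2$cumdist_category == "long"))
})

test_that("pair_speeds: arithmetic, filters, input validation", {
  flat <- flat_terrain(40)
  lc <- uniform_landcover("savanna", 40)
  trk <- list(track_id = "t1", individual_class = "community_staff",
              rainfall_mm = 0,
              points = data.frame(t = c(0, 10, 20), x = c(100, 110, 120),
                                  y = 200, ele = 300))
  pr <- pair_speeds(trk, flat, lc)
  expect_equal(pr$speed_kmh, c(3.6, 3.6))
  expect_equal(pr$landcover_label, c("savanna", "savanna"))

  # a teleporting point (100 m in 10 s = 36 km/h) is filtered and counted
  trk2 <- trk
  trk2$points <- data.frame(t = c(0, 10, 20, 30),
                            x = c(100, 110, 210, 220), y = 200, ele = 300)
  pr2 <- pair_speeds(trk2, flat, lc)
  expect_equal(nrow(pr2), 2)
  expect_equal(unname(attr(pr2, "filtered")["too_fast"]), 1)

  # a 20 s gap is filtered by the elapsed-time rule
  trk3 <- trk
  trk3$points <- data.frame(t = c(0, 10, 30, 40),
                            x = c(100, 110, 130, 140), y = 200, ele = 300)
  pr3 <- pair_speeds(trk3, flat, lc)
  expect_equal(nrow(pr3), 2)
  expect_equal(unname(attr(pr3, "filtered")["bad_dt"]), 1)

  trk4 <- trk
  trk4$points$t <- c(0, 10, 10)
  expect_error(pair_speeds(trk4, flat, lc), "t1")
  expect_error(pair_speeds(list(track_id = "t9", points = trk$points[1, ]),
                           flat, lc), "two points")
})
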