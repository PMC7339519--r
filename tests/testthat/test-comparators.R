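# Baseline methods: Euclidean constant speed, friction surface least-cost
# routing, and the method-comparison statistics.

test_that("euclidean_time arithmetic and degenerate cases", {
  expect_equal(euclidean_time(c(0, 0), c(2500, 0)), 30)
  expect_equal(euclidean_time(c(10, 10), c(10, 10)), 0)
  expect_equal(euclidean_time(list(x = 0, y = 0), list(x = 0, y = 1000),
                              speed_kmh = 4), 15)
  expect_error(euclidean_time(c(NA, 0), c(1, 1)), "finite")
})

test_that("straight-line distance never exceeds network distance", {
  rr <- mini_routes("PHC", 15)
  for (r in rr) {
    pl <- r$polyline
    chord <- sqrt(sum((pl[nrow(pl), ] - pl[1, ])^2))
    expect_lte(chord, r$length_m + 1e-9)
  }
})

test_that("cost surface: uniform cover, road burn-in, validation", {
  lc <- uniform_landcover("savanna", n = 30)
  cs <- build_cost_surface(lc)
  expect_true(all(cs$values == default_speed_table["savanna"]))
  # one straight road across the middle
  net <- make_network(data.frame(id = 1:2, x = c(0, 750), y = 400),
                      cbind(1, 2))
  cs2 <- build_cost_surface(lc, net)
  row <- 17 # y = 400 falls in row 17 (cells 25 m)
  expect_true(all(cs2$values[row, 1:30] == default_speed_table["path"]))
  expect_true(all(cs2$values[5, ] == default_speed_table["savanna"]))
  expect_error(build_cost_surface(lc, speed_table = c(savanna = 4)),
               "water")
  # water is the slowest class in the default table
  expect_equal(names(which.min(default_speed_table[lc_classes])), "water")
})

test_that("flat homogeneous least-cost time is octile-close to the chord", {
  lc <- uniform_landcover("savanna", n = 40, cell = 50)
  tab <- default_speed_table
  tab["savanna"] <- 5
  cs <- build_cost_surface(lc, speed_table = tab)
  flat <- flat_terrain(n = 40, cell = 50)
  # axis-aligned kilometre: exactly 12 min on the cell graph
  t_axis <- least_cost_time(cs, flat, c(475, 975), rbind(c(1475, 975)))
  expect_equal(t_axis, 12, tolerance = 1e-9)
  # oblique kilometre: within the 8.3% octile overshoot
  ang <- c(475 + 1000 * cos(0.35), 975 + 1000 * sin(0.35))
  # snap endpoints to cell centres so the chord is measured on the graph
  snap <- function(p) (floor(p / 50) + 0.5) * 50
  a <- snap(c(475, 975)); b <- snap(ang)
  chord_min <- sqrt(sum((b - a)^2)) / 1000 / 5 * 60
  t_ob <- least_cost_time(cs, flat, a, rbind(b))
  expect_gte(t_ob, chord_min - 1e-9)
  expect_lte(t_ob, chord_min * 1.083)
  # destination at the origin
  expect_equal(least_cost_time(cs, flat, a, rbind(a)), 0)
  expect_error(least_cost_time(cs, flat, c(-500, 0), rbind(b)), "outside")
})

test_that("least-cost equals a brute-force relaxation oracle on a 10x10 grid", {
  set.seed(13)
  n <- 10; cell <- 100
  spd <- matrix(runif(n * n, 1, 6), n, n)
  cs <- spatial_grid(spd, cell_size = cell)
  class(cs) <- c("cost_surface", class(cs))
  elev <- spatial_grid(matrix(runif(n * n, 0, 30), n, n), cell_size = cell)
  origin <- c(50, 50); dest <- rbind(c(950, 950))
  got <- least_cost_time(cs, elev, origin, dest, anisotropic = TRUE)

  # oracle: Bellman-Ford relaxation over the same 8-connected move set,
  # with weights rebuilt from first principles
  dist <- matrix(Inf, n, n)
  dist[1, 1] <- 0
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  step_t <- function(r0, c0, r1, c1) {
    len <- cell * sqrt((r1 - r0)^2 + (c1 - c0)^2)
    v <- (spd[r0, c0] + spd[r1, c1]) / 2
    grad <- (elev$values[r1, c1] - elev$values[r0, c0]) / len
    fac <- exp(-3.5 * abs(grad + 0.05)) / exp(-0.175)
    len / 1000 / (v * fac) * 60
  }
  for (sweep in seq_len(n * n)) {
    changed <- FALSE
    for (r in 1:n) for (cc in 1:n) {
      if (!is.finite(dist[r, cc])) next
      for (k in seq_len(nrow(moves))) {
        r1 <- r + moves$dr[k]; c1 <- cc + moves$dc[k]
        if (r1 < 1 || r1 > n || c1 < 1 || c1 > n) next
        cand <- dist[r, cc] + step_t(r, cc, r1, c1)
        if (cand < dist[r1, c1] - 1e-12) {
          dist[r1, c1] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  expect_equal(got, dist[10, 10], tolerance = 1e-9)
})

test_that("a fast road beats open terrain when burned in", {
  lc <- uniform_landcover("rice_field", n = 30) # slow base (2 km/h)
  flat <- flat_terrain(n = 30)
  a <- c(62.5, 387.5); b <- c(687.5, 387.5)
  t_no_road <- least_cost_time(build_cost_surface(lc), flat, a, rbind(b))
  net <- make_network(data.frame(id = 1:2, x = c(0, 750), y = 387.5),
                      cbind(1, 2))
  t_road <- least_cost_time(build_cost_surface(lc, net), flat, a, rbind(b))
  expect_lt(t_road, t_no_road)
})

test_that("anisotropic factor is direction-aware, isotropic is not", {
  up <- walkaccess:::slope_speed_factor(0.10, anisotropic = TRUE)
  down <- walkaccess:::slope_speed_factor(-0.10, anisotropic = TRUE)
  expect_false(isTRUE(all.equal(up, down)))
  expect_equal(walkaccess:::slope_speed_factor(0.10, anisotropic = FALSE),
               walkaccess:::slope_speed_factor(-0.10, anisotropic = FALSE))
  expect_equal(walkaccess:::slope_speed_factor(0), 1)
})

test_that("compare_methods: absolute-value rule and exclusions", {
  ref <- c(a = 10, b = 20, c = 30)
  same <- compare_methods(ref, list(self = ref))
  expect_equal(same$table$mean_abs_diff_min, 0)
  expect_equal(same$table$mean_rel_diff_pct, 0)

  m <- compare_methods(c(a = 20, b = 20), list(pm = c(a = 30, b = 10)))
  expect_equal(m$table$mean_abs_diff_min, 10)
  expect_equal(m$table$mean_rel_diff_pct, 50)
  expect_equal(unname(m$signed$pm), c(10, -10))

  z <- compare_methods(c(a = 0, b = 10), list(pm = c(a = 5, b = 20)))
  expect_equal(z$table$n_excluded_relative, 1)
  expect_equal(z$table$mean_rel_diff_pct, 100)

  # hand-computed 5-route spreadsheet oracle
  ref5 <- c(r1 = 10, r2 = 25, r3 = 40, r4 = 55, r5 = 100)
  eu5 <- c(r1 = 6, r2 = 20, r3 = 30, r4 = 40, r5 = 70)
  out <- compare_methods(ref5, list(euclidean = eu5))
  expect_equal(out$table$mean_abs_diff_min,
               mean(c(4, 5, 10, 15, 30)))
  expect_equal(out$table$mean_rel_diff_pct,
               mean(c(40, 20, 25, 300 / 11, 30)), tolerance = 1e-9)
  expect_error(compare_methods(ref5, list(bad = eu5[1:3])), "aligned")
})
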