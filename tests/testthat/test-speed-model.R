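# The speed model: published coefficients, exact evaluation, additive
# invariants, the backfitting fitter and the variance decomposition.

test_that("published model carries the reported coefficient set", {
  m <- published_model()
  expect_equal(m$intercept_kmh, 3.27)
  expect_equal(m$rain_per10mm, -0.06)
  expect_equal(m$longdist_effect, -0.38)
  expect_equal(unname(m$landcover_effects["water"]), -1.32)
  expect_equal(unname(m$landcover_effects["mixed"]), 0)
  expect_equal(unname(m$individual_effects["research_team"]), 1.20)
  expect_equal(unname(m$individual_effects["community_staff"]), 0)
  # calibrated variance components reproduce the reported share
  expect_equal(variance_share(m), 0.3945, tolerance = 1e-12)
})

test_that("evaluation at worked examples is exact", {
  m <- published_model()
  expect_identical(predict_speed(m), 3.27)
  expect_equal(predict_speed(m, landcover_label = "water"), 1.95)
  expect_equal(predict_speed(m, rainfall_mm = 20), 3.15)
  # extreme slope drives the predictor through the floor
  expect_equal(predict_speed(m, slope_pct = 150), m$speed_floor)
  expect_error(predict_speed(m, landcover_label = "swamp"), "swamp")
  expect_error(predict_speed(m, individual_class = "tourist"), "tourist")
  expect_error(predict_speed(m, cumdist_category = "medium"), "medium")
})

test_that("additivity, rainfall monotonicity and slope symmetry hold", {
  m <- published_model()
  labs <- segment_lc_labels
  for (a in labs) {
    for (b in labs) {
      da <- predict_speed(m, landcover_label = a) -
        predict_speed(m, landcover_label = b)
      expect_equal(da, unname(m$landcover_effects[a] - m$landcover_effects[b]),
                   tolerance = 1e-12)
    }
  }
  rain <- seq(0, 47.5, by = 2.5)
  sp <- predict_speed(m, rainfall_mm = rain)
  expect_true(all(diff(sp) <= 1e-12))
  s <- c(0.5, 3, 7, 12, 25, 40)
  expect_equal(predict_speed(m, slope_pct = s),
               predict_speed(m, slope_pct = -s), tolerance = 1e-12)
})

test_that("speed_model constructor enforces reference levels", {
  expect_error(speed_model(3, landcover_effects = c(
    water = 0, forest = 0, rice_field = 0, savanna = 0, residential = 0,
    mixed = 0.1)), "reference")
  expect_error(speed_model(3, individual_effects = c(
    community_staff = 0.5, research_team = 0, local_population = 0)),
    "reference")
  expect_error(speed_model(3, slope_smooth = list(family = "exponential",
                                                  a = 1, b = 0)), NA)
})

# deterministic factorial PairObservation table with exact model speeds
exact_pairs <- function(model, n_tracks = 6, slope_levels = c(0, 5, 12)) {
  grid <- expand.grid(track = seq_len(n_tracks),
                      slope_pct = slope_levels,
                      rainfall_mm = c(0, 20, 40),
                      cumdist_category = c("short", "long"),
                      landcover_label = segment_lc_labels,
                      individual_class = individual_classes,
                      stringsAsFactors = FALSE)
  # rainfall and class are track-level in real data, but exact recovery
  # only needs a full-rank design
  grid$track_id <- sprintf("t%02d", grid$track)
  grid$speed_kmh <- predict_speed(model,
                                  slope_pct = grid$slope_pct,
                                  rainfall_mm = grid$rainfall_mm,
                                  cumdist_category = grid$cumdist_category,
                                  landcover_label = grid$landcover_label,
                                  individual_class = grid$individual_class)
  grid
}

test_that("noiseless pairs are fitted exactly (flat and sloped)", {
  m <- noiseless(published_model())
  flat <- exact_pairs(m, slope_levels = 0)
  fit <- fit_speed_model(flat)
  expect_equal(fit$model$intercept_kmh, 3.27, tolerance = 1e-8)
  expect_equal(fit$model$rain_per10mm, -0.06, tolerance = 1e-8)
  expect_equal(fit$model$longdist_effect, -0.38, tolerance = 1e-8)
  expect_equal(fit$model$landcover_effects, m$landcover_effects,
               tolerance = 1e-8)
  expect_equal(fit$model$individual_effects, m$individual_effects,
               tolerance = 1e-8)
  expect_equal(fit$model$sigma_eps, 0, tolerance = 1e-6)

  sloped <- exact_pairs(m)
  fit2 <- fit_speed_model(sloped)
  expect_equal(fit2$model$rain_per10mm, -0.06, tolerance = 1e-6)
  expect_equal(fit2$model$longdist_effect, -0.38, tolerance = 1e-6)
  # the exponential smooth recovers its own family
  expect_equal(fit2$model$slope_smooth$a, 0.1, tolerance = 1e-3)
  expect_equal(fit2$model$slope_smooth$b, 0.05, tolerance = 1e-3)
})

test_that("fitter rejects unidentifiable designs by name", {
  m <- noiseless(published_model())
  pairs <- exact_pairs(m)
  one_track <- pairs[pairs$track_id == "t01", ]
  expect_error(fit_speed_model(one_track), "two tracks")
  no_water <- pairs[pairs$landcover_label != "water", ]
  expect_error(fit_speed_model(no_water), "water")
  no_long <- pairs[pairs$cumdist_category == "short", ]
  expect_error(fit_speed_model(no_long), "long")
  no_local <- pairs[pairs$individual_class != "local_population", ]
  expect_error(fit_speed_model(no_local), "local_population")
})

test_that("variance share trivials and error case", {
  m <- published_model()
  m$sigma_b <- 1; m$sigma_eps <- 1
  expect_equal(variance_share(m), 0.5)
  m$sigma_b <- 0
  expect_equal(variance_share(m), 0)
  m$sigma_eps <- 0
  expect_error(variance_share(m), "undefined")
})

test_that("B-spline smooth alternative reproduces the fixed effects", {
  m <- noiseless(published_model())
  pairs <- exact_pairs(m, slope_levels = seq(0, 20, by = 1))
  fit <- fit_speed_model(pairs, smooth = "bspline", spline_df = 8)
  expect_equal(fit$model$rain_per10mm, -0.06, tolerance = 1e-3)
  expect_equal(fit$model$longdist_effect, -0.38, tolerance = 1e-3)
  # the fitted spline tracks the generating exponential inside the range
  s <- seq(0, 20, by = 0.5)
  truth <- -0.1 * (exp(0.05 * s) - 1)
  got <- walkaccess:::smooth_eval(fit$model$slope_smooth, s)
  expect_lt(max(abs(got - truth)), 0.02)
})

test_that("paper-scale refit recovers every fixed effect within 3 SE", {
  d <- default_district()
  m <- published_model()
  ts <- simulate_tracks(d$cfg, d$network, d$terrain, d$landcover, m,
                        n_tracks = 168, seed = 1)
  pairs <- track_set_pairs(ts, d$terrain, d$landcover)
  fit <- fit_speed_model(pairs)
  truth <- c(intercept = m$intercept_kmh,
             rain_per10mm = m$rain_per10mm,
             longdist = m$longdist_effect,
             landcover_water = unname(m$landcover_effects["water"]),
             landcover_forest = unname(m$landcover_effects["forest"]),
             landcover_rice_field = unname(m$landcover_effects["rice_field"]),
             landcover_savanna = unname(m$landcover_effects["savanna"]),
             landcover_residential = unname(m$landcover_effects["residential"]),
             individual_research_team = unname(m$individual_effects["research_team"]),
             individual_local_population = unname(m$individual_effects["local_population"]))
  for (nm in names(truth)) {
    z <- abs(fit$coefficients[[nm]] - truth[[nm]]) / fit$standard_errors[[nm]]
    expect_lt(z, 3)
  }
  # single-replicate sanity only; the 20-replicate mean is the criterion
  expect_equal(fit$variance_share_random, 0.3945, tolerance = 0.2)
  .fixture_env$paper_fit <- fit
})

test_that("AIC prefers the full model over single-term deletions", {
  # a generating model with decisively non-null terms, so every deletion
  # must cost AIC on its own data
  gen <- speed_model(3.27,
                     slope_smooth = list(family = "exponential", a = 0.3,
                                         b = 0.06),
                     rain_per10mm = -0.3, longdist_effect = -0.8,
                     landcover_effects = c(water = -1.3, forest = 0.4,
                                           rice_field = -0.5, savanna = -0.3,
                                           residential = -0.6, mixed = 0),
                     individual_effects = c(community_staff = 0,
                                            research_team = 1.2,
                                            local_population = 1.3),
                     sigma_b = 0.3, sigma_eps = 0.8)
  d <- mini_district()
  ts <- simulate_tracks(d$cfg, d$network, d$terrain, d$landcover, gen,
                        n_tracks = 60, seed = 17, total_km = 320)
  pairs <- track_set_pairs(ts, d$terrain, d$landcover)
  full <- fit_speed_model(pairs)
  for (term in c("rainfall", "longdist", "landcover", "individual", "slope")) {
    reduced <- fit_speed_model(pairs, drop = term)
    expect_gt(AIC(reduced), AIC(full))
  }
})

test_that("fitter agrees with an independent mixed-GAM oracle", {
  d <- mini_district()
  m <- published_model()
  ts <- simulate_tracks(d$cfg, d$network, d$terrain, d$landcover, m,
                        n_tracks = 25, seed = 29, total_km = 130)
  pairs <- track_set_pairs(ts, d$terrain, d$landcover)
  fit <- fit_speed_model(pairs)

  dat <- pairs
  dat$s_abs <- abs(dat$slope_pct)
  dat$rain10 <- dat$rainfall_mm / 10
  dat$long <- as.numeric(dat$cumdist_category == "long")
  dat$landcover_label <- factor(dat$landcover_label,
                                levels = c("mixed",
                                           setdiff(segment_lc_labels, "mixed")))
  dat$individual_class <- factor(dat$individual_class,
                                 levels = individual_classes)
  dat$track <- factor(dat$track_id)
  g <- mgcv::gam(speed_kmh ~ s(s_abs) + rain10 + long + landcover_label +
                   individual_class + s(track, bs = "re"), data = dat,
                 method = "REML")
  cg <- stats::coef(g)
  expect_equal(fit$model$rain_per10mm, unname(cg["rain10"]), tolerance = 0.02)
  expect_equal(fit$model$longdist_effect, unname(cg["long"]), tolerance = 0.02)
  expect_equal(unname(fit$model$landcover_effects["water"]),
               unname(cg["landcover_labelwater"]), tolerance = 0.03)
  expect_equal(unname(fit$model$individual_effects["local_population"]),
               unname(cg["individual_classlocal_population"]),
               tolerance = 0.05)
})

test_that("fit report and serialisation round-trip", {
  m <- noiseless(published_model())
  fit <- fit_speed_model(exact_pairs(m, slope_levels = 0))
  rep <- fit_report(fit)
  expect_true(all(c("term", "estimate", "se", "p") %in% names(rep)))
  f <- tempfile(fileext = ".json")
  write_speed_model(fit$model, f)
  back <- read_speed_model(f)
  expect_equal(back$intercept_kmh, fit$model$intercept_kmh)
  expect_equal(back$landcover_effects, fit$model$landcover_effects)
})
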