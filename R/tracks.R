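# GPS track simulation. Tracks walk random routes over the footpath
# network; every 10 s the walker covers speed * 10 s metres, with speed
# drawn from the additive model (segment fixed effects + track random
# intercept + residual noise, clamped at the floor). Points carry time,
# position and terrain elevation, like OsmAnd field recordings. A
# point-dropout rate emulates GPS dropouts; dropped points create 20 s+
# pairs that the elapsed-time filter later discards. Its 0.2 default is
# calibrated so an 871 km sample walked at the model's mean speed
# (~3.5 km/h, so ~89,000 raw 10 s pairs) retains roughly 57,700 clean
# pairs — the only way a strict 10 s protocol reconciles those totals.

# unclamped linear predictor for a segment table (vectorised)
speed_linpred <- function(model, segs, individual_class, b_i = 0) {
  model$intercept_kmh +
    smooth_eval(model$slope_smooth, segs$slope_pct) +
    model$rain_per10mm * segs$rainfall_mm / 10 +
    model$longdist_effect * (segs$cumdist_category == "long") +
    unname(model$landcover_effects[segs$landcover_label]) +
    unname(model$individual_effects[individual_class]) +
    b_i
}

#' Simulate a set of GPS walking tracks
#'
#' Routes are random walks over the footpath network truncated at a target
#' length; target lengths are lognormal draws rescaled so the set totals
#' `total_km` and capped at `max_track_km` (the fitted-range ceiling).
#' Each track draws a walker class, a daily rainfall `U(0, rainfall_max)`
#' and a random intercept `N(0, sigma_b^2)`; each 10 s step draws speed
#' `max(floor, eta_segment + b_i + eps)`, `eps ~ N(0, sigma_eps^2)`, where
#' `eta_segment` is the fixed-effect predictor of the 100 m segment
#' containing the walker.
#'
#' @param cfg a [district_config()] (supplies `rainfall_max`).
#' @param network a `path_network`.
#' @param terrain,landcover district rasters.
#' @param model generating `speed_model` (its `sigma_b`, `sigma_eps` and
#'   `speed_floor` are used).
#' @param n_tracks number of tracks.
#' @param seed simulation seed (defaults to `cfg$seed`).
#' @param class_probs sampling weights over [individual_classes].
#' @param total_km target total track length; the default keeps the field
#'   campaign's 871 km per 168 tracks ratio.
#' @param max_track_km per-track length cap.
#' @param dropout probability that an emitted GPS point is lost.
#' @param dt recording interval in seconds.
#' @return a `track_set`: `tracks` (list of track objects) and `truth`
#'   (generating model plus per-track draws and per-step generator speeds,
#'   kept for recovery tests).
#' @export
simulate_tracks <- function(cfg, network, terrain, landcover, model,
                            n_tracks = 168, seed = cfg$seed,
                            class_probs = c(community_staff = 0.2,
                                            research_team = 0.4,
                                            local_population = 0.4),
                            total_km = 871 * n_tracks / 168,
                            max_track_km = 22.9,
                            dropout = 0.2, dt = 10) {
  if (!inherits(model, "speed_model")) wa_stop("`model` must be a speed_model")
  if (n_tracks < 1) wa_stop("`n_tracks` must be >= 1")
  if (dropout < 0 || dropout >= 1) wa_stop("`dropout` must be in [0, 1)")
  class_probs <- class_probs[individual_classes]
  if (anyNA(class_probs)) wa_stop("`class_probs` must be named over individual_classes")

  # adjacency for the route random walk
  adj <- split(
    data.frame(edge = c(seq_len(nrow(network$edges)), seq_len(nrow(network$edges))),
               to = c(network$edges$to, network$edges$from)),
    c(network$edges$from, network$edges$to)
  )

  with_seed(seed, {
    len <- stats::rlnorm(n_tracks, meanlog = log(4000), sdlog = 0.8)
    len <- pmin(pmax(len, 500), max_track_km * 1000)
    len <- len * (total_km * 1000) / sum(len)
    len <- pmin(len, max_track_km * 1000)

    cls <- sample(individual_classes, n_tracks, replace = TRUE,
                  prob = class_probs)
    rain <- stats::runif(n_tracks, 0, cfg$rainfall_max)
    b_i <- stats::rnorm(n_tracks, sd = model$sigma_b)

    tracks <- vector("list", n_tracks)
    truth_speeds <- vector("list", n_tracks)
    realized <- numeric(n_tracks)
    for (i in seq_len(n_tracks)) {
      pl <- random_walk_polyline(network, adj, len[i])
      segs <- segment_route(pl, terrain, landcover, rainfall_mm = rain[i])
      eta <- speed_linpred(model, segs, cls[i], b_i = b_i[i])
      total <- segs$end_m[nrow(segs)]

      n_guess <- ceiling(total / (max(mean(eta), 0.5) * dt / 3.6)) * 2 + 50
      eps <- stats::rnorm(n_guess, sd = model$sigma_eps)
      seg_starts <- segs$start_m
      nsegs <- nrow(segs)
      dists <- numeric(n_guess); speeds <- numeric(n_guess)
      d <- 0; k <- 0L
      repeat {
        if (k + 1L > length(eps)) {
          eps <- c(eps, stats::rnorm(n_guess, sd = model$sigma_eps))
          dists <- c(dists, numeric(n_guess))
          speeds <- c(speeds, numeric(n_guess))
        }
        # covariates come from the segment holding the interval MIDPOINT,
        # matching the pair -> segment rule used when tracks are read back;
        # one fixed-point pass resolves the midpoint/speed circularity
        si <- min(findInterval(d, seg_starts), nsegs)
        v <- max(model$speed_floor, eta[si] + eps[k + 1L])
        si <- min(findInterval(d + v * dt / 7.2, seg_starts), nsegs)
        v <- max(model$speed_floor, eta[si] + eps[k + 1L])
        step <- v * dt / 3.6
        if (d + step > total) break
        k <- k + 1L
        d <- d + step
        dists[k] <- d; speeds[k] <- v
      }
      dists <- dists[seq_len(k)]; speeds <- speeds[seq_len(k)]
      stations <- c(0, dists)
      pts <- points_along(pl, stations)
      ele <- grid_interp(terrain, pts[, 1], pts[, 2])
      points <- data.frame(t = dt * (seq_along(stations) - 1),
                           x = pts[, 1], y = pts[, 2], ele = ele)
      if (dropout > 0) {
        keep <- stats::runif(nrow(points)) >= dropout
        if (sum(keep) < 2L) keep[1:2] <- TRUE
        points <- points[keep, , drop = FALSE]
        rownames(points) <- NULL
        # the track starts at its first surviving fix
        points$t <- points$t - points$t[1]
      }
      realized[i] <- if (length(dists)) dists[length(dists)] else 0
      tracks[[i]] <- list(track_id = sprintf("t%03d", i),
                          individual_class = cls[i],
                          rainfall_mm = rain[i],
                          points = points)
      truth_speeds[[i]] <- speeds
    }
    ts <- list(
      tracks = tracks,
      truth = list(
        model = model,
        tracks = data.frame(track_id = sprintf("t%03d", seq_len(n_tracks)),
                            individual_class = cls, rainfall_mm = rain,
                            b_i = b_i, target_length_m = len,
                            realized_length_m = realized,
                            stringsAsFactors = FALSE),
        step_speeds = truth_speeds
      ),
      seed = seed
    )
    class(ts) <- "track_set"
    ts
  })
}

#' @export
print.track_set <- function(x, ...) {
  tot <- sum(x$truth$tracks$realized_length_m) / 1000
  npts <- sum(vapply(x$tracks, function(t) nrow(t$points), integer(1)))
  cat(sprintf("<track_set> %d tracks, %.1f km walked, %d GPS points (seed %d)\n",
              length(x$tracks), tot, npts, x$seed))
  invisible(x)
}

# random walk over the junction graph, avoiding immediate backtracking,
# truncated to target_m of polyline
random_walk_polyline <- function(network, adj, target_m) {
  start <- sample(network$nodes$id, 1)
  node <- start
  prev_edge <- -1L
  pieces <- list()
  got <- 0
  while (got < target_m) {
    opts <- adj[[as.character(node)]]
    if (is.null(opts) || nrow(opts) == 0L) break
    cand <- opts[opts$edge != prev_edge, , drop = FALSE]
    if (nrow(cand) == 0L) cand <- opts # dead end: turn back
    pick <- cand[sample.int(nrow(cand), 1), ]
    ge <- network$geoms[[pick$edge]]
    if (network$edges$from[pick$edge] != node) ge <- rev_polyline(ge)
    pieces[[length(pieces) + 1L]] <- ge
    got <- got + network$edges$length[pick$edge]
    prev_edge <- pick$edge
    node <- pick$to
  }
  poly <- do.call(rbind, pieces)
  keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-9)
  poly <- as_polyline(poly[keep, , drop = FALSE])
  sub_polyline(poly, 0, min(target_m, polyline_length(poly)))
}

#' Simulate-and-refit parameter-recovery experiment
#'
#' Runs the generator/fitter round trip: one synthetic district, then
#' `n_replicates` independent track sets simulated from `model` and refit
#' with [fit_speed_model()]. This is the calibration experiment behind the
#' rainfall, fatigue and variance-share recovery checks.
#'
#' @param n_replicates number of simulate/refit rounds.
#' @param seed master seed; the district uses it directly and replicate
#'   `i` simulates with `seed * 1000 + i`.
#' @param cfg district configuration (defaults to [district_config()] with
#'   `seed`).
#' @param model generating model (default [published_model()]).
#' @param n_tracks tracks per replicate.
#' @param smooth passed to [fit_speed_model()].
#' @param ... further arguments to [simulate_tracks()].
#' @return data frame with one row per replicate: estimated intercept,
#'   rainfall and long-distance coefficients, sigma_b, sigma_eps,
#'   variance share, pair count; generating values in
#'   `attr(, "truth")`.
#' @export
recovery_experiment <- function(n_replicates = 20, seed = 1,
                                cfg = district_config(seed = seed),
                                model = published_model(),
                                n_tracks = 168,
                                smooth = "exponential", ...) {
  terrain <- generate_terrain(cfg)
  sites <- generate_sites(cfg, terrain)
  landcover <- generate_landcover(cfg, terrain, sites)
  network <- generate_network(cfg, terrain, sites)
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    ts <- simulate_tracks(cfg, network, terrain, landcover, model,
                          n_tracks = n_tracks, seed = seed * 1000 + i, ...)
    pairs <- track_set_pairs(ts, terrain, landcover)
    fit <- fit_speed_model(pairs, smooth = smooth)
    lc <- fit$model$landcover_effects
    ind <- fit$model$individual_effects
    rows[[i]] <- data.frame(
      replicate = i,
      intercept = fit$model$intercept_kmh,
      rain_per10mm = fit$model$rain_per10mm,
      longdist_effect = fit$model$longdist_effect,
      water = unname(lc["water"]), forest = unname(lc["forest"]),
      rice_field = unname(lc["rice_field"]),
      savanna = unname(lc["savanna"]),
      residential = unname(lc["residential"]),
      research_team = unname(ind["research_team"]),
      local_population = unname(ind["local_population"]),
      sigma_b = fit$model$sigma_b,
      sigma_eps = fit$model$sigma_eps,
      variance_share = fit$variance_share_random,
      n_pairs = fit$n_pairs
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- c(intercept = model$intercept_kmh,
                          rain_per10mm = model$rain_per10mm,
                          longdist_effect = model$longdist_effect,
                          variance_share = unname(variance_share(model)))
  out
}
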