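# Operational shell: a resolved configuration object, staged pipeline
# (simulate -> route -> fit-speed -> predict-time -> compare -> summarize)
# and a small CLI dispatcher. Every stage writes its artifacts plus a
# seed/config-hash sidecar, and `run-all` chains the stages
# deterministically.

#' Build a pipeline configuration
#'
#' @param out_dir artifact directory (created if absent).
#' @param district list of overrides for [district_config()].
#' @param n_tracks simulated GPS tracks.
#' @param model_source `"published"` uses [published_model()] for
#'   prediction; `"fitted"` refits from the simulated tracks first.
#' @param individual_class walker class used for population predictions.
#' @param rain_max_mm rainy-scenario ceiling.
#' @param distance_edges_km,time_edges_min accessibility bin edges.
#' @param vulnerability_threshold_min dual-vulnerability cutoff.
#' @param euclidean_speed_kmh constant speed of the Euclidean baseline.
#' @param crs list with `lat0`, `lon0` anchoring the planar CRS.
#' @param seed master seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "walkaccess-run",
                            district = list(),
                            n_tracks = 50,
                            model_source = c("published", "fitted"),
                            individual_class = "community_staff",
                            rain_max_mm = 47.5,
                            distance_edges_km = distance_bins_km,
                            time_edges_min = time_bins_min,
                            vulnerability_threshold_min = 60,
                            euclidean_speed_kmh = 5,
                            crs = list(lat0 = -21.3, lon0 = 47.6),
                            seed = 1L) {
  model_source <- match.arg(model_source)
  district$seed <- seed
  cfg <- list(out_dir = out_dir,
              district = do.call(district_config, district),
              n_tracks = n_tracks,
              model_source = model_source,
              individual_class = individual_class,
              rain_max_mm = rain_max_mm,
              distance_edges_km = distance_edges_km,
              time_edges_min = time_edges_min,
              vulnerability_threshold_min = vulnerability_threshold_min,
              euclidean_speed_kmh = euclidean_speed_kmh,
              crs = crs,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- j[intersect(names(j), names(formals(pipeline_config)))]
  if (!is.null(args$district)) args$district <- as.list(args$district)
  if (!is.null(args$crs)) args$crs <- as.list(args$crs)
  do.call(pipeline_config, args)
}

log_line <- function(state, stage, msg, ...) {
  rec <- list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage = stage, message = sprintf(msg, ...))
  line <- as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  cat(line, "\n", sep = "", file = state$log_path, append = TRUE)
  message("[", stage, "] ", rec$message)
}

side <- function(cfg, path) {
  write_sidecar(path, cfg$seed, unclass(cfg)["seed" != names(unclass(cfg))])
  path
}

#' Run the accessibility pipeline
#'
#' Stages: `simulate` (district + GPS tracks), `route` (nearest-facility
#' routes), `fit-speed` (refit from simulated tracks), `predict-time`
#' (dry/rain scenario times), `compare` (Euclidean + friction baselines),
#' `summarize` (accessibility tables + vulnerability). `run-all` chains
#' them. Stage failures halt with the stage name in the error.
#'
#' @param cfg a [pipeline_config()].
#' @param stages character vector of stages (default all, in order).
#' @return (invisibly) the artifact directory.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "route", "fit-speed",
                                         "predict-time", "compare",
                                         "summarize")) {
  if (!inherits(cfg, "pipeline_config")) wa_stop("`cfg` must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$log_path <- file.path(cfg$out_dir, "run_log.jsonl")
  jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (st in stages) {
    res <- tryCatch(run_stage(cfg, st, state),
                    error = function(e) {
                      stop("pipeline stage '", st, "' failed: ",
                           conditionMessage(e), call. = FALSE)
                    })
  }
  invisible(cfg$out_dir)
}

# lazily (re)load district artifacts from a previous stage
load_district <- function(cfg, state) {
  if (!is.null(state$terrain)) return(invisible())
  dc <- cfg$district
  state$terrain <- generate_terrain(dc)
  state$sites <- generate_sites(dc, state$terrain)
  state$landcover <- generate_landcover(dc, state$terrain, state$sites)
  state$network <- generate_network(dc, state$terrain, state$sites)
  invisible()
}

run_stage <- function(cfg, stage, state) {
  od <- cfg$out_dir
  dc <- cfg$district
  switch(stage,
    "simulate" = {
      load_district(cfg, state)
      log_line(state, stage, "district: %d sites, %.1f km of paths",
               nrow(state$sites), sum(state$network$edges$length) / 1000)
      side(cfg, write_ascii_grid(state$terrain, file.path(od, "terrain.asc")))
      side(cfg, write_ascii_grid(state$landcover, file.path(od, "landcover.asc")))
      side(cfg, write_network_geojson(state$network, file.path(od, "network.geojson")))
      side(cfg, write_sites_geojson(state$sites, file.path(od, "sites.geojson")))
      state$tracks <- simulate_tracks(dc, state$network, state$terrain,
                                      state$landcover, published_model(),
                                      n_tracks = cfg$n_tracks,
                                      seed = cfg$seed + 11L)
      side(cfg, write_gpx_tracks(state$tracks, file.path(od, "tracks.gpx"),
                                 lat0 = cfg$crs$lat0, lon0 = cfg$crs$lon0))
      rainfall <- state$tracks$truth$tracks[, c("track_id", "rainfall_mm")]
      utils::write.csv(rainfall, file.path(od, "rainfall.csv"),
                       row.names = FALSE)
      log_line(state, stage, "%d tracks, %.1f km walked",
               length(state$tracks$tracks),
               sum(state$tracks$truth$tracks$realized_length_m) / 1000)
    },
    "route" = {
      load_district(cfg, state)
      b <- state$sites[state$sites$kind == "building", ]
      f <- state$sites[state$sites$kind != "building", ]
      state$routes_phc <- nearest_facility_routes(b, f, state$network, "PHC")
      state$routes_chs <- nearest_facility_routes(b, f, state$network, "CHS")
      dist_tab <- rbind(routes_distance_table(state$routes_phc),
                        routes_distance_table(state$routes_chs))
      utils::write.csv(dist_tab, side(cfg, file.path(od, "distances.csv")),
                       row.names = FALSE)
      side(cfg, write_routes_geojson(c(state$routes_phc, state$routes_chs),
                                     file.path(od, "routes.geojson")))
      log_line(state, stage, "%d routes (PHC + CHS)", nrow(dist_tab))
    },
    "fit-speed" = {
      load_district(cfg, state)
      if (is.null(state$tracks)) run_stage(cfg, "simulate", state)
      pairs <- track_set_pairs(state$tracks, state$terrain, state$landcover)
      state$fit <- fit_speed_model(pairs)
      utils::write.csv(fit_report(state$fit),
                       side(cfg, file.path(od, "speed_fit.csv")),
                       row.names = FALSE)
      side(cfg, write_speed_model(state$fit$model,
                                  file.path(od, "speed_model_fitted.json")))
      log_line(state, stage,
               "fit on %d pairs from %d tracks; variance share %.1f%%",
               state$fit$n_pairs, state$fit$n_tracks,
               100 * state$fit$variance_share_random)
    },
    "predict-time" = {
      load_district(cfg, state)
      if (is.null(state$routes_phc)) run_stage(cfg, "route", state)
      model <- if (cfg$model_source == "published") published_model() else {
        if (is.null(state$fit)) run_stage(cfg, "fit-speed", state)
        state$fit$model
      }
      state$model <- model
      state$times_phc <- scenario_times(state$routes_phc, model,
                                        state$terrain, state$landcover,
                                        rain_max_mm = cfg$rain_max_mm,
                                        individual_class = cfg$individual_class)
      state$times_chs <- scenario_times(state$routes_chs, model,
                                        state$terrain, state$landcover,
                                        rain_max_mm = cfg$rain_max_mm,
                                        individual_class = cfg$individual_class)
      utils::write.csv(rbind(state$times_phc, state$times_chs),
                       side(cfg, file.path(od, "travel_times.csv")),
                       row.names = FALSE)
      log_line(state, stage, "predicted %d + %d routes",
               nrow(state$times_phc), nrow(state$times_chs))
    },
    "compare" = {
      if (is.null(state$times_phc)) run_stage(cfg, "predict-time", state)
      b <- state$sites[state$sites$kind == "building", ]
      f <- state$sites[state$sites$kind != "building", ]
      surf <- build_cost_surface(state$landcover, state$network)
      tabs <- list()
      for (kind in c("PHC", "CHS")) {
        tt <- if (kind == "PHC") state$times_phc else state$times_chs
        fk <- f[f$kind == kind, ]
        ref <- stats::setNames(tt$time_dry_min, tt$origin_id)
        eu <- vapply(seq_len(nrow(b)), function(i) {
          min(vapply(seq_len(nrow(fk)), function(j)
            euclidean_time(b[i, ], fk[j, ], cfg$euclidean_speed_kmh),
            numeric(1)))
        }, numeric(1))
        names(eu) <- b$id
        fr <- friction_times(surf, state$terrain, b, fk)
        cmp <- compare_methods(ref, list(euclidean = eu[names(ref)],
                                         friction = fr[names(ref)]))
        tab <- cmp$table
        tab$facility_kind <- kind
        tabs[[kind]] <- tab
      }
      utils::write.csv(do.call(rbind, tabs),
                       side(cfg, file.path(od, "method_comparison.csv")),
                       row.names = FALSE)
      log_line(state, stage, "comparison table written")
    },
    "summarize" = {
      if (is.null(state$times_phc)) run_stage(cfg, "predict-time", state)
      b <- state$sites[state$sites$kind == "building", ]
      w <- b$population_weight
      tabs <- list()
      for (kind in c("PHC", "CHS")) {
        tt <- if (kind == "PHC") state$times_phc else state$times_chs
        tt <- tt[match(b$id, tt$origin_id), ]
        tabs[[paste0(kind, "_dist")]] <-
          table_to_df(bin_population(tt$distance_m / 1000,
                                     cfg$distance_edges_km, w,
                                     facility_kind = kind,
                                     metric = "distance_km",
                                     scenario = "n/a"))
        for (sc in c("dry", "rain")) {
          v <- if (sc == "dry") tt$time_dry_min else tt$time_rain_min
          tabs[[paste0(kind, "_time_", sc)]] <-
            table_to_df(bin_population(v, cfg$time_edges_min, w,
                                       facility_kind = kind,
                                       metric = "time_min", scenario = sc))
        }
      }
      utils::write.csv(do.call(rbind, tabs),
                       side(cfg, file.path(od, "accessibility_tables.csv")),
                       row.names = FALSE)
      # dual vulnerability under the rain scenario
      tv <- data.frame(origin_id = b$id,
                       x = b$x, y = b$y,
                       time_phc_min = state$times_phc$time_rain_min[
                         match(b$id, state$times_phc$origin_id)],
                       time_chs_min = state$times_chs$time_rain_min[
                         match(b$id, state$times_chs$origin_id)])
      vuln <- vulnerable_sites(tv, cfg$vulnerability_threshold_min, "rain")
      tv$vulnerable <- tv$origin_id %in% vuln$origin_id
      utils::write.csv(tv, side(cfg, file.path(od, "vulnerability.csv")),
                       row.names = FALSE)
      # IDW visualisation surface of dry PHC time
      viz <- idw_surface(b, state$times_phc$time_dry_min[
        match(b$id, state$times_phc$origin_id)],
        coarse_grid(state$terrain, 4))
      side(cfg, write_ascii_grid(viz, file.path(od, "phc_time_idw.asc")))
      log_line(state, stage, "%d/%d buildings dually vulnerable (> %g min)",
               nrow(vuln), nrow(b), cfg$vulnerability_threshold_min)
    },
    wa_stop("unknown pipeline stage: ", stage)
  )
  invisible()
}

table_to_df <- function(tab) {
  df <- as.data.frame(tab)
  df$facility_kind <- attr(tab, "facility_kind")
  df$metric <- attr(tab, "metric")
  df$scenario <- attr(tab, "scenario")
  df
}

# friction least-cost minutes from each building to its nearest facility
friction_times <- function(surface, terrain, buildings, facilities) {
  g <- cell_graph(surface, terrain, anisotropic = TRUE)
  nr <- nrow(surface$values)
  cell_of <- function(df) {
    ix <- grid_cell_index(surface, df$x, df$y)
    (ix[, "col"] - 1) * nr + ix[, "row"]
  }
  bv <- cell_of(buildings); fv <- cell_of(facilities)
  ub <- unique(bv)
  d <- igraph::distances(g, v = as.character(unique(fv)),
                         to = as.character(ub), mode = "out")
  out <- apply(d, 2, min)[match(bv, ub)]
  stats::setNames(out, buildings$id)
}

# downsampled copy of a grid (block mean) for cheap visualisation surfaces
coarse_grid <- function(g, factor = 4) {
  nr <- floor(nrow(g$values) / factor) * factor
  nc <- floor(ncol(g$values) / factor) * factor
  v <- g$values[seq_len(nr), seq_len(nc), drop = FALSE]
  vr <- rowsum(v, rep(seq_len(nr / factor), each = factor))
  vc <- t(rowsum(t(vr), rep(seq_len(nc / factor), each = factor)))
  spatial_grid(vc / factor^2, origin = g$origin,
               cell_size = g$cell_size * factor)
}

#' Command-line entry point
#'
#' `Rscript -e 'walkaccess::cli_main()' <subcommand> [--config=path]
#' [--out=dir] [--seed=N] [--tracks=N]`. Subcommands are the pipeline
#' stages plus `run-all`. Config-file values win over flags (with a
#' warning) except for `--out`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return invisibly, the artifact directory.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: walkaccess <simulate|route|fit-speed|predict-time|compare|summarize|run-all>",
        "[--config=path] [--out=dir] [--seed=N] [--tracks=N]\n")
    return(invisible(NULL))
  }
  sub <- args[1]
  opt <- function(name, default = NULL) {
    hit <- grep(paste0("^--", name, "="), args, value = TRUE)
    if (length(hit)) sub(paste0("^--", name, "="), "", hit[1]) else default
  }
  if (!is.null(opt("config"))) {
    cfg <- read_pipeline_config(opt("config"))
    for (flag in c("seed", "tracks")) {
      if (!is.null(opt(flag))) {
        warning("--", flag, " ignored: config file wins on conflict")
      }
    }
    if (!is.null(opt("out"))) cfg$out_dir <- opt("out")
  } else {
    cfg <- pipeline_config(
      out_dir = opt("out", "walkaccess-run"),
      n_tracks = as.integer(opt("tracks", "50")),
      seed = as.integer(opt("seed", "1"))
    )
  }
  stages <- if (sub == "run-all") c("simulate", "route", "fit-speed",
                                    "predict-time", "compare", "summarize")
            else sub
  run_pipeline(cfg, stages)
}
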