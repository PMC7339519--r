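# File formats. All geometry is written in the local planar CRS declared
# in the pipeline config: GeoJSON coordinates are planar metres (the WGS84
# default of the format is deliberately overridden and documented in the
# files themselves via a `crs` member), while GPX — whose schema demands
# lat/lon — goes through a local equirectangular tangent-plane mapping.

# --- Esri ASCII grid ------------------------------------------------------

#' Write a grid as Esri ASCII (.asc)
#'
#' @param grid a `spatial_grid`.
#' @param path output file.
#' @param nodata value standing in for NA cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  # rows top-first
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 10),
                                  collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path .asc file.
#' @param classes optional class names to mark the grid categorical.
#' @return a `spatial_grid`; NODATA cells become NA.
#' @export
read_ascii_grid <- function(path, classes = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    val <- if (length(kv) == 2L) suppressWarnings(as.numeric(kv[2])) else NA
    if (!is.finite(val)) wa_stop("malformed header at line ", i, " of ", path)
    hdr[[tolower(kv[1])]] <- val
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    wa_stop("header of ", path, " lacks: ",
            paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    wa_stop(path, ": expected ", nr * nc, " cells, found ", length(vals))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE] # back to row 1 = south
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  if (!is.null(classes)) storage.mode(m) <- "integer"
  spatial_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner),
               cell_size = hdr$cellsize, classes = classes)
}

# --- GeoJSON --------------------------------------------------------------

geojson_skeleton <- function(features, crs_note = "local planar metres") {
  list(type = "FeatureCollection",
       crs = list(type = "name",
                  properties = list(name = paste0("urn:local:", crs_note))),
       features = features)
}

#' Write a path network as GeoJSON LineStrings
#' @param network a `path_network`.
#' @param path output file.
#' @export
write_network_geojson <- function(network, path) {
  feats <- lapply(seq_len(nrow(network$edges)), function(i) {
    e <- network$edges[i, ]
    list(type = "Feature",
         properties = list(id = e$id, from = e$from, to = e$to,
                           length_m = e$length),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(network$geoms[[i]], 1,
                                                    as.numeric,
                                                    simplify = FALSE))))
  })
  jsonlite::write_json(geojson_skeleton(feats), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a path network from GeoJSON
#' @param path file written by [write_network_geojson()].
#' @return a `path_network`.
#' @export
read_network_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  feats <- j$features
  if (is.null(feats)) wa_stop(path, ": not a FeatureCollection")
  edges <- data.frame(id = integer(), from = integer(), to = integer())
  geoms <- list()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    if (f$geometry$type != "LineString") {
      wa_stop(path, ": feature ", k, " is not a LineString")
    }
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    edges <- rbind(edges, data.frame(id = f$properties$id,
                                     from = f$properties$from,
                                     to = f$properties$to))
    geoms[[length(geoms) + 1L]] <- as_polyline(coords)
  }
  ord <- order(edges$id)
  edges <- edges[ord, , drop = FALSE]
  geoms <- geoms[ord]
  node_ids <- sort(unique(c(edges$from, edges$to)))
  # node coordinates from edge endpoints
  nx <- ny <- rep(NA_real_, length(node_ids))
  for (k in seq_along(geoms)) {
    i <- match(edges$from[k], node_ids); j <- match(edges$to[k], node_ids)
    nx[i] <- geoms[[k]][1, 1]; ny[i] <- geoms[[k]][1, 2]
    nx[j] <- geoms[[k]][nrow(geoms[[k]]), 1]
    ny[j] <- geoms[[k]][nrow(geoms[[k]]), 2]
  }
  path_network(data.frame(id = node_ids, x = nx, y = ny),
               edges, geoms)
}

#' Write sites as GeoJSON Points
#' @param sites a `site_set`.
#' @param path output file.
#' @export
write_sites_geojson <- function(sites, path) {
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    list(type = "Feature",
         properties = list(id = s$id, kind = s$kind,
                           population_weight = s$population_weight),
         geometry = list(type = "Point",
                         coordinates = c(s$x, s$y)))
  })
  jsonlite::write_json(geojson_skeleton(feats), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read sites from GeoJSON
#' @param path file written by [write_sites_geojson()].
#' @return a `site_set` (without cluster metadata).
#' @export
read_sites_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$features)) wa_stop(path, ": not a FeatureCollection")
  rows <- lapply(seq_along(j$features), function(k) {
    f <- j$features[[k]]
    if (f$geometry$type != "Point") wa_stop(path, ": feature ", k, " is not a Point")
    data.frame(id = as.character(f$properties$id),
               x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]],
               kind = as.character(f$properties$kind),
               population_weight = as.numeric(f$properties$population_weight),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("site_set", "data.frame")
  out
}

#' Write routes as GeoJSON LineStrings
#' @param routes list of `route` objects.
#' @param path output file.
#' @export
write_routes_geojson <- function(routes, path) {
  feats <- lapply(routes, function(r) {
    if (is.null(r$polyline)) return(NULL)
    list(type = "Feature",
         properties = list(origin = r$origin_id, destination = r$dest_id,
                           length_m = r$length_m),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(r$polyline, 1, as.numeric,
                                                    simplify = FALSE))))
  })
  feats <- feats[!vapply(feats, is.null, logical(1))]
  jsonlite::write_json(geojson_skeleton(feats), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# --- GPX ------------------------------------------------------------------

# local equirectangular mapping between planar metres and lat/lon around a
# reference point; adequate at district scale and exactly invertible
planar_to_geo <- function(x, y, lat0 = -21.3, lon0 = 47.6) {
  lat <- lat0 + y / 110540
  lon <- lon0 + x / (111320 * cos(lat0 * pi / 180))
  cbind(lon = lon, lat = lat)
}

geo_to_planar <- function(lon, lat, lat0 = -21.3, lon0 = 47.6) {
  y <- (lat - lat0) * 110540
  x <- (lon - lon0) * 111320 * cos(lat0 * pi / 180)
  cbind(x = x, y = y)
}

#' Write a track set as GPX 1.1
#'
#' One `<trk>` per track with `<trkseg>/<trkpt>` points carrying `ele` and
#' ISO-8601 `time`. Walker class and daily rainfall travel in `<desc>` as
#' `key=value` pairs so the file round-trips without sidecars.
#'
#' @param tracks a `track_set` or list of track objects.
#' @param path output file.
#' @param t0 POSIXct epoch for point times.
#' @param lat0,lon0 reference point of the planar CRS.
#' @export
write_gpx_tracks <- function(tracks, path, t0 = as.POSIXct("2018-09-01 06:00:00",
                                                           tz = "UTC"),
                             lat0 = -21.3, lon0 = 47.6) {
  trk <- if (inherits(tracks, "track_set")) tracks$tracks else tracks
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "walkaccess",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  for (tr in trk) {
    tnode <- xml2::xml_add_child(doc, "trk")
    xml2::xml_add_child(tnode, "name", tr$track_id)
    xml2::xml_add_child(tnode, "desc",
                        sprintf("individual_class=%s;rainfall_mm=%.6f",
                                tr$individual_class, tr$rainfall_mm))
    seg <- xml2::xml_add_child(tnode, "trkseg")
    ll <- planar_to_geo(tr$points$x, tr$points$y, lat0, lon0)
    times <- format(t0 + tr$points$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    for (i in seq_len(nrow(tr$points))) {
      pt <- xml2::xml_add_child(seg, "trkpt",
                                lat = sprintf("%.9f", ll[i, "lat"]),
                                lon = sprintf("%.9f", ll[i, "lon"]))
      xml2::xml_add_child(pt, "ele", sprintf("%.3f", tr$points$ele[i]))
      xml2::xml_add_child(pt, "time", times[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read GPX 1.1 tracks
#'
#' Every track point must carry a `time` element; a missing time is
#' rejected with the track and point index named.
#'
#' @param path GPX file.
#' @param lat0,lon0 reference point of the planar CRS (must match the
#'   writer's).
#' @return list of track objects (`track_id`, `individual_class`,
#'   `rainfall_mm`, `points`).
#' @export
read_gpx_tracks <- function(path, lat0 = -21.3, lon0 = 47.6) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  out <- list()
  for (tnode in xml2::xml_find_all(doc, ".//trk")) {
    name <- xml2::xml_text(xml2::xml_find_first(tnode, "./name"))
    desc <- xml2::xml_text(xml2::xml_find_first(tnode, "./desc"))
    meta <- parse_kv(desc)
    pts <- xml2::xml_find_all(tnode, ".//trkpt")
    if (length(pts) == 0L) wa_stop(path, ": track ", name, " has no points")
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    ele <- as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./ele")))
    tstr <- xml2::xml_find_first(pts, "./time")
    missing_t <- vapply(seq_along(tstr), function(i)
      inherits(tstr[[i]], "xml_missing"), logical(1))
    if (any(missing_t)) {
      wa_stop(path, ": track ", name, " point ", which(missing_t)[1],
              " lacks a <time> element")
    }
    tt <- as.POSIXct(xml2::xml_text(tstr), format = "%Y-%m-%dT%H:%M:%SZ",
                     tz = "UTC")
    xy <- geo_to_planar(lon, lat, lat0, lon0)
    out[[length(out) + 1L]] <- list(
      track_id = name,
      individual_class = meta[["individual_class"]],
      rainfall_mm = as.numeric(meta[["rainfall_mm"]]),
      points = data.frame(t = as.numeric(tt) - as.numeric(tt[1]),
                          x = xy[, "x"], y = xy[, "y"], ele = ele)
    )
  }
  out
}

parse_kv <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

# --- model JSON -----------------------------------------------------------

#' Serialise a speed model to JSON
#' @param model a `speed_model`.
#' @param path output file.
#' @export
write_speed_model <- function(model, path) {
  obj <- unclass(model)
  # named effect vectors must serialise as JSON objects, not bare arrays
  obj$landcover_effects <- as.list(obj$landcover_effects)
  obj$individual_effects <- as.list(obj$individual_effects)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a speed model from JSON
#' @param path file written by [write_speed_model()].
#' @return a `speed_model`.
#' @export
read_speed_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sm <- as.list(j$slope_smooth)
  if (identical(sm$family, "bspline")) {
    sm$boundary <- as.numeric(sm$boundary)
    sm$knots <- as.numeric(sm$knots)
    sm$coef <- as.numeric(sm$coef)
  }
  speed_model(intercept_kmh = j$intercept_kmh,
              slope_smooth = sm,
              rain_per10mm = j$rain_per10mm,
              longdist_effect = j$longdist_effect,
              landcover_effects = unlist(j$landcover_effects),
              individual_effects = unlist(j$individual_effects),
              sigma_b = j$sigma_b, sigma_eps = j$sigma_eps,
              speed_floor = j$speed_floor)
}

# --- sidecars -------------------------------------------------------------

#' Write a provenance sidecar next to an output file
#'
#' Records the producing seed and a hash of the resolved configuration, so
#' every artifact is traceable to its run.
#' @param path the artifact the sidecar describes.
#' @param seed producing seed.
#' @param config list; hashed (FNV-1a over its JSON form) and recorded.
#' @export
write_sidecar <- function(path, seed, config) {
  cfg_json <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                            digits = NA, force = TRUE))
  jsonlite::write_json(
    list(artifact = basename(path), seed = seed,
         config_hash = fnv1a_hash(cfg_json)),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(paste0(path, ".meta.json"))
}
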