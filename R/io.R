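# Vector, tabular and report input/output.
#
# GeoJSON is the vector dialect (read and written with jsonlite); every
# writer records the projected CRS as a legacy "crs" member so that
# round-trips are self-describing.  All thresholds in the scoring tables
# are metric, so geographic (degree) layers are rejected at load time.

GEOGRAPHIC_CRS <- c("EPSG:4326", "EPSG:4269", "EPSG:4267", "OGC:CRS84",
                    "CRS84", "URN:OGC:DEF:CRS:OGC:1.3:CRS84")

check_projected_crs <- function(crs_name) {
  if (is.null(crs_name)) {
    warning("no CRS declared; assuming projected metric coordinates")
    return(invisible(NULL))
  }
  if (toupper(crs_name) %in% GEOGRAPHIC_CRS)
    stop("projected metric CRS required (layer declares geographic CRS ",
         crs_name, ")")
  invisible(crs_name)
}

geojson_geometry <- function(type, coords) {
  switch(type,
    Point = list(type = "Point", coordinates = as.numeric(coords)),
    LineString = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(coords)),
                                           function(i) as.numeric(coords[i, ]))),
    Polygon = {
      ring <- close_ring(coords)
      ring <- rbind(ring, ring[1L, , drop = FALSE])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) as.numeric(ring[i, ]))))
    },
    stop("unsupported geometry type ", type))
}

#' Write features to a GeoJSON file
#'
#' @param features list of features, each `list(type=, coords=, properties=)`
#'   with `type` one of Point/LineString/Polygon and `coords` a coordinate
#'   matrix (or length-2 vector for points).
#' @param path output file.
#' @param crs CRS identifier recorded in the file (e.g. `"EPSG:3071"`).
#' @export
write_geojson <- function(features, path, crs = "EPSG:3071") {
  fc <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = crs)),
    features = lapply(features, function(f) {
      list(type = "Feature",
           properties = if (length(f$properties)) f$properties else structure(list(), names = character()),
           geometry = geojson_geometry(f$type, f$coords))
    }))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a GeoJSON FeatureCollection
#'
#' @param path input file.
#' @return list with `crs` (may be NULL) and `features`, each
#'   `list(type=, coords=, properties=)`.
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$type) || js$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  crs <- js$crs$properties$name
  feats <- lapply(js$features, function(f) {
    g <- f$geometry
    coords <- switch(g$type,
      Point = unlist(g$coordinates),
      LineString = do.call(rbind, lapply(g$coordinates, unlist)),
      Polygon = close_ring(do.call(rbind, lapply(g$coordinates[[1L]], unlist))),
      stop("unsupported geometry type ", g$type))
    list(type = g$type, coords = coords, properties = f$properties)
  })
  list(crs = crs, features = feats)
}

feature_kind <- function(f) {
  k <- f$properties$kind
  if (is.null(k)) NA_character_ else as.character(k)
}

#' Load a site plan from GeoJSON
#'
#' Expects features tagged via a `kind` property: one `boundary` polygon,
#' any number of `tree` / `building` obstacle polygons and optionally one
#' `stream` channel polygon.
#'
#' @param path GeoJSON file.
#' @param config an [assessment_config()]; its focus-corridor width (when
#'   present in the file) is not consulted -- the file value wins.
#' @return a [site_plan()].
#' @export
load_site_plan <- function(path, config = assessment_config()) {
  gj <- read_geojson(path)
  check_projected_crs(gj$crs)
  kinds <- vapply(gj$features, feature_kind, character(1))
  bi <- which(kinds == "boundary")
  if (length(bi) != 1L) stop("missing required layer: exactly one 'boundary' polygon expected")
  oi <- which(kinds %in% c("tree", "building"))
  si <- which(kinds == "stream")
  fw <- gj$features[[bi]]$properties$focus_corridor_width_m
  site_plan(boundary = gj$features[[bi]]$coords,
            obstacles = lapply(gj$features[oi], `[[`, "coords"),
            obstacle_kind = kinds[oi],
            stream_channel = if (length(si)) gj$features[[si[1L]]]$coords else NULL,
            focus_corridor_width_m = if (is.null(fw)) 10 else fw)
}

#' Save a site plan to GeoJSON
#' @param site a [site_plan()].
#' @param path output file.
#' @param crs CRS identifier to record.
#' @export
save_site_plan <- function(site, path, crs = "EPSG:3071") {
  feats <- list(list(type = "Polygon", coords = site$boundary,
                     properties = list(kind = "boundary",
                                       focus_corridor_width_m = site$focus_corridor_width_m)))
  for (i in seq_along(site$obstacles))
    feats[[length(feats) + 1L]] <- list(type = "Polygon", coords = site$obstacles[[i]],
                                        properties = list(kind = site$obstacle_kind[i]))
  if (!is.null(site$stream_channel))
    feats[[length(feats) + 1L]] <- list(type = "Polygon", coords = site$stream_channel,
                                        properties = list(kind = "stream"))
  write_geojson(feats, path, crs)
}

#' Load bank geometry from GeoJSON
#'
#' Expects `kind`-tagged features: `left_bank`, `right_bank` (LineStrings,
#' required), optional `left_bank_top` / `right_bank_top` LineStrings,
#' `island` polygons, and `inlet` / `outlet` points (required).
#'
#' @param path GeoJSON file.
#' @return a [bank_geometry()].
#' @export
load_bank_geometry <- function(path) {
  gj <- read_geojson(path)
  check_projected_crs(gj$crs)
  kinds <- vapply(gj$features, feature_kind, character(1))
  pick1 <- function(kind, required = TRUE) {
    i <- which(kinds == kind)
    if (length(i) == 0L) {
      if (required) stop("missing required layer: ", kind)
      return(NULL)
    }
    gj$features[[i[1L]]]$coords
  }
  bank_geometry(left_bank = pick1("left_bank"), right_bank = pick1("right_bank"),
                left_bank_top = pick1("left_bank_top", FALSE),
                right_bank_top = pick1("right_bank_top", FALSE),
                islands = lapply(gj$features[kinds == "island"], `[[`, "coords"),
                inlet = pick1("inlet"), outlet = pick1("outlet"))
}

#' Save bank geometry to GeoJSON
#' @param banks a [bank_geometry()].
#' @param path output file.
#' @param crs CRS identifier to record.
#' @export
save_bank_geometry <- function(banks, path, crs = "EPSG:3071") {
  feats <- list(
    list(type = "LineString", coords = banks$left_bank, properties = list(kind = "left_bank")),
    list(type = "LineString", coords = banks$right_bank, properties = list(kind = "right_bank")),
    list(type = "Point", coords = banks$inlet, properties = list(kind = "inlet")),
    list(type = "Point", coords = banks$outlet, properties = list(kind = "outlet")))
  if (!is.null(banks$left_bank_top))
    feats[[length(feats) + 1L]] <- list(type = "LineString", coords = banks$left_bank_top,
                                        properties = list(kind = "left_bank_top"))
  if (!is.null(banks$right_bank_top))
    feats[[length(feats) + 1L]] <- list(type = "LineString", coords = banks$right_bank_top,
                                        properties = list(kind = "right_bank_top"))
  for (isl in banks$islands)
    feats[[length(feats) + 1L]] <- list(type = "Polygon", coords = isl,
                                        properties = list(kind = "island"))
  write_geojson(feats, path, crs)
}

#' Load habitat layers from GeoJSON (+ optional bed-point CSV)
#'
#' Polygon features carry `kind` (erosion, veg_buffer, instream_cover,
#' woody_debris) and `side` (left/right) properties; bed elevation samples
#' are Point features of kind `bed_point` with an `elev` property.  A
#' constant water-surface elevation may be stored as a `water_surface_elev`
#' property on any feature.
#'
#' @param path GeoJSON file.
#' @return a [layer_set()].
#' @export
load_layer_set <- function(path) {
  gj <- read_geojson(path)
  check_projected_crs(gj$crs)
  kinds <- vapply(gj$features, feature_kind, character(1))
  per_side <- function(kind) {
    out <- sided()
    for (f in gj$features[kinds == kind]) {
      side <- f$properties$side
      if (is.null(side) || !side %in% c("left", "right"))
        stop("layer feature of kind '", kind, "' lacks a left/right 'side' property")
      out[[side]][[length(out[[side]]) + 1L]] <- f$coords
    }
    out
  }
  bp <- gj$features[kinds == "bed_point"]
  bed_points <- if (length(bp))
    data.frame(x = vapply(bp, function(f) f$coords[1L], 1),
               y = vapply(bp, function(f) f$coords[2L], 1),
               elev = vapply(bp, function(f) as.numeric(f$properties$elev), 1))
  ws <- NULL
  for (f in gj$features) {
    v <- f$properties$water_surface_elev
    if (!is.null(v)) { ws <- as.numeric(v); break }
  }
  layer_set(erosion = per_side("erosion"), veg_buffer = per_side("veg_buffer"),
            instream_cover = per_side("instream_cover"),
            woody_debris = per_side("woody_debris"),
            bed_points = bed_points, water_surface = ws)
}

#' Save habitat layers to GeoJSON
#' @param layers a [layer_set()].
#' @param path output file.
#' @param crs CRS identifier to record.
#' @export
save_layer_set <- function(layers, path, crs = "EPSG:3071") {
  feats <- list()
  for (kind in c("erosion", "veg_buffer", "instream_cover", "woody_debris"))
    for (side in c("left", "right"))
      for (pg in layers[[kind]][[side]])
        feats[[length(feats) + 1L]] <- list(type = "Polygon", coords = pg,
                                            properties = list(kind = kind, side = side))
  if (!is.null(layers$bed_points))
    for (i in seq_len(nrow(layers$bed_points)))
      feats[[length(feats) + 1L]] <- list(
        type = "Point",
        coords = c(layers$bed_points$x[i], layers$bed_points$y[i]),
        properties = list(kind = "bed_point", elev = layers$bed_points$elev[i]))
  # a constant water surface rides on the first feature
  if (length(feats) && is.numeric(layers$water_surface) &&
      length(layers$water_surface) == 1L)
    feats[[1L]]$properties$water_surface_elev <- layers$water_surface
  write_geojson(feats, path, crs)
}

STATION_COLUMNS <- c("s", "x", "y", "W", "D", "BT", "E_left", "E_right",
                     "B_left", "B_right", "F_left", "F_right",
                     "wet_fraction", "white_fraction", "v_proxy")

#' Write a station table to CSV
#'
#' One row per centerline station, fixed column order, with a comment
#' header documenting units.
#'
#' @param records station data frame (see [extract_stations()]).
#' @param path output CSV file.
#' @export
write_station_table <- function(records, path) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L)
    stop("station table is empty; refusing to write an empty file")
  records <- validate_stations(records)
  for (cc in setdiff(STATION_COLUMNS, names(records))) records[[cc]] <- NA_real_
  records <- records[, STATION_COLUMNS]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# streamhab station table; s/x/y and all widths/depths in",
                    " metres; wet_fraction and white_fraction in [0,1];",
                    " v_proxy dimensionless"), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a station table written by [write_station_table()]
#' @param path CSV file.
#' @return station data frame.
#' @export
read_station_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_stations(utils::read.csv(path, comment.char = "#"))
}

#' Write an assessment report to JSON
#' @param report a `habitat_report` (see [assess_continuous()]).
#' @param path output JSON file.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an assessment report written by [write_report()]
#' @param path JSON file.
#' @return a `habitat_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  js$total <- as.numeric(js$total)
  report <- structure(js, class = "habitat_report")
  validate_report(report)
  report
}

validate_report <- function(report) {
  need <- paste0("M", 2:9)
  miss <- setdiff(need, names(report$metrics))
  if (length(miss))
    stop("report missing metric(s): ", paste(miss, collapse = ", "))
  if (is.null(report$gradient_class) || !report$gradient_class %in% c("H", "M"))
    stop("report lacks a gradient class")
  if (is.null(report$total) || is.null(report$overall))
    stop("report lacks total score or overall class")
  invisible(report)
}

#' Read an assessment or flight configuration file (YAML or JSON)
#'
#' Field names must match the arguments of [assessment_config()] or
#' [flight_config()]; unknown fields raise an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param type which configuration to build.
#' @return an [assessment_config()] or [flight_config()].
#' @export
read_config <- function(path, type = c("assessment", "flight")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  ctor <- if (type == "assessment") assessment_config else flight_config
  unknown <- setdiff(names(vals), names(formals(ctor)))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(ctor, vals)
}
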