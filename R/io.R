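# Readers and writers: CSV layer dialects, GeoJSON roads/points, the
# network CSV pair, YAML/JSON config and the run manifest. CSV is the
# canonical result format (fixed headers, UTF-8, "." decimal). Every writer
# emits a header comment line carrying run metadata (seed, config hash);
# readers tolerate and preserve it.

place_types <- function() names(place_population_defaults())
facility_kinds <- function() c("hospital", "health_promoting_hospital", "care_center")

#' Construct/validate a places layer
#'
#' Unknown place types are rejected with a row-level message; missing
#' populations are filled from [place_population_defaults()].
#'
#' @param places data frame with columns `id, x, y, place_type` and
#'   optionally `population`.
#' @return validated data frame.
#' @export
places_frame <- function(places) {
  req <- c("id", "x", "y", "place_type")
  if (!all(req %in% names(places))) {
    abort_scpath(sprintf("places layer needs columns: %s",
                         paste(req, collapse = ", ")))
  }
  places$id <- as.character(places$id)
  if (anyDuplicated(places$id)) abort_scpath("duplicate place ids")
  places$place_type <- normalize_class(places$place_type)
  bad <- which(!places$place_type %in% place_types())
  if (length(bad) > 0) {
    abort_scpath(sprintf("unknown place type '%s' at row %d (id %s)",
                         places$place_type[bad[1]], bad[1], places$id[bad[1]]))
  }
  if (is.null(places$population)) places$population <- NA_real_
  fill <- is.na(places$population)
  places$population[fill] <-
    unname(place_population_defaults()[places$place_type[fill]])
  places
}

#' Construct/validate a facilities layer
#'
#' @param facilities data frame with columns `id, x, y, kind` and optionally
#'   `has_poct`.
#' @param require_care_center enforce exactly one facility of kind
#'   `care_center` (default TRUE).
#' @return validated data frame.
#' @export
facilities_frame <- function(facilities, require_care_center = TRUE) {
  req <- c("id", "x", "y", "kind")
  if (!all(req %in% names(facilities))) {
    abort_scpath(sprintf("facilities layer needs columns: %s",
                         paste(req, collapse = ", ")))
  }
  facilities$id <- as.character(facilities$id)
  if (anyDuplicated(facilities$id)) abort_scpath("duplicate facility ids")
  facilities$kind <- normalize_class(facilities$kind)
  bad <- which(!facilities$kind %in% facility_kinds())
  if (length(bad) > 0) {
    abort_scpath(sprintf("unknown facility kind '%s' at row %d (id %s)",
                         facilities$kind[bad[1]], bad[1], facilities$id[bad[1]]))
  }
  if (is.null(facilities$has_poct)) facilities$has_poct <- FALSE
  facilities$has_poct <- as.logical(facilities$has_poct)
  if (require_care_center && sum(facilities$kind == "care_center") != 1) {
    abort_scpath("facility roster must contain exactly one care_center")
  }
  facilities
}

scp_header <- function(meta) {
  if (length(meta) == 0) return("# scpath")
  paste0("# scpath ", paste(sprintf("%s=%s", names(meta), unname(meta)),
                            collapse = " "))
}

#' Write a result table as CSV with a metadata header comment
#'
#' @param x data frame.
#' @param path output file.
#' @param meta named character vector written into the `# scpath` header
#'   (e.g. seed, config hash).
#' @export
write_scp_csv <- function(x, path, meta = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(scp_header(meta), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_scp_csv()]
#'
#' Comment header lines are preserved on the result as attribute
#' `scp_meta`.
#'
#' @param path input file.
#' @return data frame with attribute `scp_meta` (the header lines).
#' @export
read_scp_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "scp_meta") <- hdr
  df
}

# ---- WKT LINESTRING (tiny dialect used by the roads CSV) -------------------

format_wkt_linestring <- function(coords) {
  sprintf("LINESTRING (%s)",
          paste(sprintf("%.6f %.6f", coords[, 1], coords[, 2]), collapse = ", "))
}

parse_wkt_linestring <- function(wkt) {
  body <- sub("^\\s*LINESTRING\\s*\\(", "", wkt)
  body <- sub("\\)\\s*$", "", body)
  if (identical(body, wkt)) abort_scpath(sprintf("not a WKT LINESTRING: %s", wkt))
  pts <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[p != ""])))
  if (ncol(m) != 2 || anyNA(m)) abort_scpath("malformed LINESTRING coordinates")
  m
}

#' Read roads from CSV (`segment_id, highway, wkt`)
#' @param path input file.
#' @return roads data frame (see [roads_frame()]).
#' @export
read_roads_csv <- function(path) {
  df <- read_scp_csv(path)
  req <- c("segment_id", "highway", "wkt")
  if (!all(req %in% names(df))) {
    abort_scpath(sprintf("roads CSV needs columns: %s", paste(req, collapse = ", ")))
  }
  geom <- lapply(df$wkt, parse_wkt_linestring)
  roads_frame(df$segment_id, df$highway, geom)
}

#' Write roads to CSV (`segment_id, highway, wkt`)
#' @param roads roads data frame.
#' @param path output file.
#' @param meta header metadata, see [write_scp_csv()].
#' @export
write_roads_csv <- function(roads, path, meta = character(0)) {
  df <- data.frame(
    segment_id = roads$id, highway = roads$highway,
    wkt = vapply(roads$geometry, format_wkt_linestring, character(1)),
    stringsAsFactors = FALSE
  )
  write_scp_csv(df, path, meta)
}

#' Read roads from a GeoJSON FeatureCollection of LineStrings
#'
#' Features must carry a `highway` property; feature `id` (or an `id`
#' property) names the segment.
#'
#' @param path input file.
#' @return roads data frame.
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort_scpath("roads GeoJSON must be a FeatureCollection")
  }
  feats <- gj$features
  ids <- character(length(feats)); cls <- character(length(feats))
  geom <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    if (!identical(f$geometry$type, "LineString")) {
      abort_scpath(sprintf("feature %d is not a LineString", k))
    }
    ids[k] <- as.character(f$id %||% f$properties$id %||% sprintf("R%04d", k))
    cls[k] <- f$properties$highway %||%
      abort_scpath(sprintf("feature %d lacks a 'highway' property", k))
    geom[[k]] <- do.call(rbind, lapply(f$geometry$coordinates,
                                       function(p) as.numeric(unlist(p))))
  }
  roads_frame(ids, cls, geom)
}

#' Write roads as GeoJSON
#' @param roads roads data frame.
#' @param path output file.
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(seq_len(nrow(roads)), function(k) {
    g <- roads$geometry[[k]]
    list(
      type = "Feature", id = roads$id[k],
      properties = list(highway = roads$highway[k]),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(g)), function(r) c(g[r, 1], g[r, 2]))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a point layer from CSV
#'
#' Places: `id, x, y, type[, population]`. Facilities:
#' `id, x, y, kind[, has_poct]`.
#'
#' @param path input file.
#' @param layer `"places"` or `"facilities"`.
#' @param ... passed to the layer validator.
#' @return validated layer data frame.
#' @export
read_points_csv <- function(path, layer = c("places", "facilities"), ...) {
  layer <- match.arg(layer)
  df <- read_scp_csv(path)
  if (layer == "places") {
    if ("type" %in% names(df) && !"place_type" %in% names(df)) {
      names(df)[names(df) == "type"] <- "place_type"
    }
    places_frame(df)
  } else {
    facilities_frame(df, ...)
  }
}

#' Write a point layer to CSV
#' @param x layer data frame.
#' @param path output file.
#' @param meta header metadata.
#' @export
write_points_csv <- function(x, path, meta = character(0)) {
  write_scp_csv(x, path, meta)
}

#' Read all three layers
#'
#' @param paths named list/vector with entries `roads`, `places`,
#'   `facilities`; the roads path may be `.csv` or `.geojson`/`.json`.
#' @return list with `roads`, `places`, `facilities`.
#' @export
read_layers <- function(paths) {
  for (nm in c("roads", "places", "facilities")) {
    p <- paths[[nm]]
    if (is.null(p)) abort_scpath(sprintf("missing input path for '%s'", nm))
    if (!file.exists(p)) abort_scpath(sprintf("input file not found: %s", p))
  }
  roads <- if (grepl("\\.(geojson|json)$", paths[["roads"]], ignore.case = TRUE)) {
    read_roads_geojson(paths[["roads"]])
  } else {
    read_roads_csv(paths[["roads"]])
  }
  list(
    roads = roads,
    places = read_points_csv(paths[["places"]], "places"),
    facilities = read_points_csv(paths[["facilities"]], "facilities")
  )
}

#' Write all three layers of a region to a directory
#'
#' @param region an `scp_region` (or list with `roads`, `places`,
#'   `facilities`).
#' @param dir output directory (created if absent).
#' @param meta header metadata.
#' @return named vector of the written paths.
#' @export
write_layers <- function(region, dir, meta = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(roads = file.path(dir, "roads.csv"),
             places = file.path(dir, "places.csv"),
             facilities = file.path(dir, "facilities.csv"))
  write_roads_csv(region$roads, paths[["roads"]], meta)
  write_points_csv(region$places, paths[["places"]], meta)
  write_points_csv(region$facilities, paths[["facilities"]], meta)
  paths
}

#' Export a network as a junctions/segments CSV pair
#'
#' `junctions.csv`: `id,x,y`; `segments.csv`:
#' `id,u,v,class,length_m,speed_mph,travel_time_min` plus a `wkt` geometry
#' column so the network round-trips exactly.
#'
#' @param network a `road_network`.
#' @param dir output directory.
#' @param meta header metadata.
#' @return named vector of written paths.
#' @export
write_network_csv <- function(network, dir, meta = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jp <- file.path(dir, "junctions.csv")
  sp <- file.path(dir, "segments.csv")
  ap <- file.path(dir, "attachment.csv")
  write_scp_csv(network$junctions, jp, meta)
  seg <- network$segments
  seg$wkt <- vapply(seg$geometry, format_wkt_linestring, character(1))
  seg$geometry <- NULL
  write_scp_csv(seg, sp, meta)
  write_scp_csv(
    data.frame(point_id = names(network$attachment),
               junction_id = unname(network$attachment),
               stringsAsFactors = FALSE),
    ap, meta)
  c(junctions = jp, segments = sp, attachment = ap)
}

#' Read a network back from its CSV pair
#' @param dir directory holding `junctions.csv`, `segments.csv` and
#'   optionally `attachment.csv`.
#' @return a `road_network`.
#' @export
read_network_csv <- function(dir) {
  junctions <- read_scp_csv(file.path(dir, "junctions.csv"))
  seg <- read_scp_csv(file.path(dir, "segments.csv"))
  geom <- if ("wkt" %in% names(seg)) {
    lapply(seg$wkt, parse_wkt_linestring)
  } else {
    lapply(seq_len(nrow(seg)), function(k) {
      rbind(as.matrix(junctions[match(seg$u[k], junctions$id), c("x", "y")]),
            as.matrix(junctions[match(seg$v[k], junctions$id), c("x", "y")]))
    })
  }
  seg$wkt <- NULL
  seg$geometry <- I(geom)
  attachment <- character(0)
  ap <- file.path(dir, "attachment.csv")
  if (file.exists(ap)) {
    a <- read_scp_csv(ap)
    attachment <- stats::setNames(as.character(a$junction_id),
                                  as.character(a$point_id))
  }
  new_road_network(junctions, seg, attachment)
}

#' Read a run configuration (YAML or JSON)
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_scpath(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Stable short hash of a configuration object
#'
#' Polynomial rolling hash (base 31, modulus 2^31 - 1) over the canonical
#' JSON serialization; used to stamp outputs so runs are traceable to their
#' configuration.
#'
#' @param x any jsonlite-serializable object.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- Reduce(function(acc, b) (acc * 31 + b) %% 2147483647, bytes, 0)
  sprintf("%08x", as.integer(h))
}

#' Write a machine-readable run manifest
#'
#' Records inputs, configuration hash, seed and versions for
#' reproducibility.
#'
#' @param path output JSON file.
#' @param inputs named list/vector of input paths.
#' @param config configuration object.
#' @param seed integer seed used for the run.
#' @export
write_manifest <- function(path, inputs, config, seed) {
  jsonlite::write_json(list(
    inputs = as.list(inputs),
    config_hash = config_hash(config),
    seed = seed,
    r_version = R.version.string,
    scpath_version = as.character(utils::packageVersion("scpath"))
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
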