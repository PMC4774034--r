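#' Road polyline input constructor
#'
#' Assembles raw road polylines into the data frame consumed by
#' [build_network()]. Geometry is a list column of n x 2 coordinate
#' matrices in planar meters.
#'
#' @param id character vector of segment ids (unique).
#' @param highway character vector of road class labels (see [speed_table()]).
#' @param geometry list of numeric matrices, each with >= 2 rows and 2 columns.
#' @return a `data.frame` with columns `id`, `highway`, `geometry`.
#' @export
roads_frame <- function(id, highway, geometry) {
  id <- as.character(id)
  if (anyDuplicated(id)) abort_scpath("duplicate road segment ids")
  ok <- vapply(geometry, function(g) is.matrix(g) && nrow(g) >= 2 && ncol(g) == 2,
               logical(1))
  if (!all(ok)) {
    abort_scpath(sprintf("malformed geometry for road id(s): %s",
                         paste(id[!ok], collapse = ", ")))
  }
  assign_speed(highway)  # validates classes, errors on unknown labels
  data.frame(id = id, highway = normalize_class(highway),
             geometry = I(unname(geometry)), stringsAsFactors = FALSE)
}

#' Build a routable travel-time network from road polylines
#'
#' Vertices of the input polylines lying within `tolerance_m` of one another
#' are merged (single linkage) into shared junctions, mirroring the GIS
#' "integrate" step that guarantees connectivity of crowd-sourced road data.
#' Polylines are split wherever a merged vertex is shared with another
#' polyline (or is a polyline endpoint), so that roads crossing at merged
#' vertices become mutually traversable. Each resulting segment carries its
#' arc length, the class speed from `speeds`, and the travel time in minutes.
#' The network is undirected and has no turn restrictions.
#'
#' @param roads data frame from [roads_frame()] (columns `id`, `highway`,
#'   `geometry`).
#' @param tolerance_m snap tolerance in meters (default 10).
#' @param speeds speed lookup, see [speed_table()].
#' @return a `road_network` object: list with `junctions` (data frame
#'   `id,x,y`), `segments` (data frame `id,u,v,class,length_m,speed_mph,`
#'   `travel_time_min` plus a `geometry` list column), and `attachment`
#'   (named character vector mapping external point ids to junction ids).
#' @export
build_network <- function(roads, tolerance_m = 10, speeds = speed_table()) {
  stopifnot(is.data.frame(roads), tolerance_m >= 0)
  n_road <- nrow(roads)
  if (n_road == 0) abort_scpath("no road polylines supplied")

  # flatten all vertices, remembering source road and position
  verts <- do.call(rbind, lapply(seq_len(n_road), function(i) {
    g <- roads$geometry[[i]]
    cbind(road = i, pos = seq_len(nrow(g)), g)
  }))
  coords <- verts[, 3:4, drop = FALSE]
  cl <- cluster_points(coords, tolerance_m)
  nc <- max(cl)

  # cluster representative = mean coordinate of members (positional by id)
  rep_x <- as.vector(tapply(coords[, 1], factor(cl, levels = seq_len(nc)), mean))
  rep_y <- as.vector(tapply(coords[, 2], factor(cl, levels = seq_len(nc)), mean))

  # a cluster is a junction if it holds a polyline endpoint or more than one
  # vertex (shared/merged vertices make crossing roads mutually traversable)
  n_vert_per_road <- vapply(roads$geometry, nrow, integer(1))
  is_end <- verts[, "pos"] == 1 | verts[, "pos"] == n_vert_per_road[verts[, "road"]]
  has_end <- rep(FALSE, nc); has_end[cl[is_end]] <- TRUE
  multiplicity <- tabulate(cl, nbins = nc)
  is_junction_cl <- has_end | multiplicity >= 2

  seg_id <- character(0); seg_u <- character(0); seg_v <- character(0)
  seg_class <- character(0); seg_geom <- list()
  dropped <- character(0)
  jid_of_cluster <- rep(NA_character_, max(cl))

  vert_cl <- split(cl, verts[, "road"])
  for (i in seq_len(n_road)) {
    cls <- vert_cl[[as.character(i)]]
    snapped <- cbind(rep_x[cls], rep_y[cls])
    # drop consecutive vertices collapsed into the same cluster
    keep <- c(TRUE, cls[-1] != cls[-length(cls)])
    cls <- cls[keep]; snapped <- snapped[keep, , drop = FALSE]
    if (length(cls) < 2) {
      dropped <- c(dropped, roads$id[i])
      next
    }
    cut_at <- sort(unique(c(1, which(is_junction_cl[cls]), length(cls))))
    pieces <- length(cut_at) - 1
    for (p in seq_len(pieces)) {
      idx <- seq(cut_at[p], cut_at[p + 1])
      g <- snapped[idx, , drop = FALSE]
      if (polyline_length(g) <= 0) next
      seg_id <- c(seg_id, if (pieces == 1) roads$id[i] else
        sprintf("%s.%d", roads$id[i], p))
      seg_u <- c(seg_u, as.character(cls[idx[1]]))
      seg_v <- c(seg_v, as.character(cls[idx[length(idx)]]))
      seg_class <- c(seg_class, roads$highway[i])
      seg_geom <- c(seg_geom, list(unname(g)))
    }
  }
  if (length(dropped) > 0) {
    warning(sprintf("dropped %d zero-length segment(s) after merging: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (length(seg_id) == 0) abort_scpath("no segments remain after merging")

  used_cl <- sort(unique(as.integer(c(seg_u, seg_v))))
  ord <- used_cl[order(rep_x[used_cl], rep_y[used_cl])]
  jid_of_cluster[ord] <- sprintf("J%d", seq_along(ord))

  junctions <- data.frame(
    id = jid_of_cluster[ord],
    x = rep_x[ord],
    y = rep_y[ord],
    stringsAsFactors = FALSE
  )
  length_m <- vapply(seg_geom, polyline_length, numeric(1))
  speed <- assign_speed(seg_class, speeds)
  segments <- data.frame(
    id = seg_id,
    u = jid_of_cluster[as.integer(seg_u)],
    v = jid_of_cluster[as.integer(seg_v)],
    class = seg_class,
    length_m = length_m,
    speed_mph = speed,
    travel_time_min = travel_time_min(length_m, speed),
    stringsAsFactors = FALSE
  )
  segments$geometry <- I(seg_geom)
  new_road_network(junctions, segments, character(0))
}

new_road_network <- function(junctions, segments, attachment) {
  stopifnot(all(segments$u %in% junctions$id), all(segments$v %in% junctions$id))
  structure(
    list(junctions = junctions, segments = segments, attachment = attachment),
    class = "road_network"
  )
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf(
    "<road_network> %d junctions, %d segments (%d connectors), %d attached points\n",
    nrow(x$junctions), nrow(x$segments),
    sum(x$segments$class == "connector"), length(x$attachment)))
  invisible(x)
}

#' Attach an off-network point with a connector edge
#'
#' Joins an external point (a populated place or health facility) to the
#' network with a straight connector segment (class `"connector"`, 35 mph)
#' to the nearest point on the nearest existing road segment. The target
#' segment is split at the foot point into two segments that preserve its
#' total length. If the point falls within `junction_tolerance_m` of an
#' existing junction it is attached there directly and no connector is
#' created. Ties between equidistant segments are broken by the smallest
#' segment id.
#'
#' @param network a `road_network`.
#' @param point_id external id recorded in the attachment map.
#' @param coord numeric length-2 planar coordinate (meters).
#' @param junction_tolerance_m direct-attachment tolerance (default 1e-6 m).
#' @param speeds speed lookup used for the connector class.
#' @return the updated `road_network`.
#' @export
connect_point <- function(network, point_id, coord,
                          junction_tolerance_m = 1e-6,
                          speeds = speed_table()) {
  stopifnot(inherits(network, "road_network"), length(coord) == 2)
  if (nrow(network$segments) == 0) abort_scpath("cannot attach to an empty network")
  point_id <- as.character(point_id)
  if (point_id %in% names(network$attachment)) {
    abort_scpath(sprintf("point '%s' is already attached", point_id))
  }
  coord <- as.numeric(coord)

  # coincident with an existing junction -> attach directly
  dj <- sqrt((network$junctions$x - coord[1])^2 + (network$junctions$y - coord[2])^2)
  if (min(dj) <= junction_tolerance_m) {
    j <- network$junctions$id[which.min(dj)]
    network$attachment[point_id] <- j
    return(network)
  }

  pr <- nearest_projection(network, coord)
  seg <- network$segments[pr$segment, ]

  foot <- pr$point
  # if the foot lands on (within tolerance of) one of the segment's end
  # junctions, reuse that junction instead of splitting
  ends <- network$junctions[match(c(seg$u, seg$v), network$junctions$id), ]
  de <- sqrt((ends$x - foot[1])^2 + (ends$y - foot[2])^2)
  if (min(de) <= junction_tolerance_m) {
    foot_jid <- ends$id[which.min(de)]
  } else {
    foot_jid <- sprintf("JF_%s", point_id)
    halves <- split_polyline(seg$geometry[[1]], pr$piece, pr$t)
    network$junctions <- rbind(network$junctions, data.frame(
      id = foot_jid, x = foot[1], y = foot[2], stringsAsFactors = FALSE))
    mk <- function(suffix, g, u, v) {
      len <- polyline_length(g)
      out <- data.frame(
        id = sprintf("%s.%s", seg$id, suffix), u = u, v = v, class = seg$class,
        length_m = len, speed_mph = seg$speed_mph,
        travel_time_min = travel_time_min(len, seg$speed_mph),
        stringsAsFactors = FALSE)
      out$geometry <- I(list(g))
      out
    }
    keep <- network$segments$id != seg$id
    network$segments <- rbind(
      network$segments[keep, ],
      mk("1", halves$first, seg$u, foot_jid),
      mk("2", halves$second, foot_jid, seg$v)
    )
  }

  conn_len <- sqrt(sum((coord - foot)^2))
  if (conn_len <= junction_tolerance_m) {
    # point lies on the segment itself: attach at the foot junction
    network$attachment[point_id] <- foot_jid
    return(network)
  }
  point_jid <- sprintf("JP_%s", point_id)
  network$junctions <- rbind(network$junctions, data.frame(
    id = point_jid, x = coord[1], y = coord[2], stringsAsFactors = FALSE))
  conn_speed <- assign_speed("connector", speeds)
  conn <- data.frame(
    id = sprintf("C_%s", point_id), u = point_jid, v = foot_jid,
    class = "connector", length_m = conn_len, speed_mph = conn_speed,
    travel_time_min = travel_time_min(conn_len, conn_speed),
    stringsAsFactors = FALSE)
  conn$geometry <- I(list(rbind(coord, foot)))
  network$segments <- rbind(network$segments, conn)
  network$attachment[point_id] <- point_jid
  rownames(network$segments) <- NULL
  rownames(network$junctions) <- NULL
  network
}

#' Attach many points at once
#'
#' @param network a `road_network`.
#' @param points data frame with columns `id`, `x`, `y`.
#' @param ... passed to [connect_point()].
#' @return the updated `road_network`.
#' @export
connect_points <- function(network, points, ...) {
  for (i in seq_len(nrow(points))) {
    network <- connect_point(network, points$id[i], c(points$x[i], points$y[i]), ...)
  }
  network
}

#' Summary of connector edges
#'
#' Reports how many synthetic connector segments the network holds and their
#' total, mean and maximum length in miles. With no connectors all lengths
#' are reported as 0 and `empty` is `TRUE`.
#'
#' @param network a `road_network`, or a numeric vector of connector lengths
#'   in meters.
#' @return list with `count`, `total_miles`, `mean_miles`, `max_miles`,
#'   `empty`.
#' @export
connector_report <- function(network) {
  lengths_m <- if (inherits(network, "road_network")) {
    network$segments$length_m[network$segments$class == "connector"]
  } else {
    as.numeric(network)
  }
  n <- length(lengths_m)
  if (n == 0) {
    return(list(count = 0L, total_miles = 0, mean_miles = 0, max_miles = 0,
                empty = TRUE))
  }
  mi <- lengths_m / METERS_PER_MILE
  list(count = n, total_miles = sum(mi), mean_miles = sum(mi) / n,
       max_miles = max(mi), empty = FALSE)
}

#' Convert a road network to an igraph graph
#'
#' Undirected, edge weight = segment travel time in minutes.
#'
#' @param network a `road_network`.
#' @return an igraph object whose vertex names are junction ids.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "road_network"))
  igraph::graph_from_data_frame(
    d = data.frame(from = network$segments$u, to = network$segments$v,
                   weight = network$segments$travel_time_min,
                   id = network$segments$id, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = network$junctions
  )
}

#' Check that all origin-destination routes exist
#'
#' @param network a `road_network`.
#' @param origin_ids,destination_ids attached point ids (or junction ids).
#' @return data frame of unreachable `(origin, destination)` pairs; zero
#'   rows when the network supports every route.
#' @export
validate_connectivity <- function(network, origin_ids, destination_ids) {
  m <- travel_time_matrix(network, origin_ids, destination_ids)
  bad <- which(is.infinite(m), arr.ind = TRUE)
  data.frame(
    origin = origin_ids[bad[, 1]],
    destination = destination_ids[bad[, 2]],
    stringsAsFactors = FALSE
  )
}

#' Total length of all segments, meters
#' @param network a `road_network`.
#' @return total length in meters.
#' @export
network_length_m <- function(network) sum(network$segments$length_m)
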