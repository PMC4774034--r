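# Two-stage spatial care path routing: origin -> closest diagnosis site
# (POCT) -> the single tertiary care center.

resolve_junction <- function(network, ids) {
  ids <- as.character(ids)
  out <- network$attachment[ids]
  miss <- is.na(out)
  if (any(miss)) {
    direct <- ids[miss] %in% network$junctions$id
    out[miss][direct] <- ids[miss][direct]
    if (!all(direct)) {
      abort_scpath(sprintf("id(s) not attached to the network: %s",
                           paste(ids[miss][!direct], collapse = ", ")))
    }
  }
  unname(out)
}

#' Travel-time matrix between attached points
#'
#' One multi-source Dijkstra pass over the undirected travel-time network.
#' Unreachable pairs are `Inf`.
#'
#' @param network a `road_network`.
#' @param from_ids,to_ids attached point ids (or raw junction ids).
#' @return numeric matrix of minutes, `dimnames = list(from_ids, to_ids)`.
#' @export
travel_time_matrix <- function(network, from_ids, to_ids) {
  g <- as_igraph(network)
  fj <- resolve_junction(network, from_ids)
  tj <- resolve_junction(network, to_ids)
  m <- igraph::distances(g, v = unique(fj), to = unique(tj),
                         weights = igraph::E(g)$weight, algorithm = "dijkstra")
  out <- m[match(fj, rownames(m)), match(tj, colnames(m)), drop = FALSE]
  dimnames(out) <- list(as.character(from_ids), as.character(to_ids))
  out
}

#' Fastest travel time between two attached points
#'
#' @param network a `road_network`.
#' @param a,b attached point ids (or junction ids).
#' @return minutes along the fastest route; `Inf` if unreachable.
#' @export
shortest_time <- function(network, a, b) {
  travel_time_matrix(network, a, b)[1, 1]
}

#' Closest facility by network travel time
#'
#' Ties are broken by the smallest facility id (lexicographic).
#'
#' @param network a `road_network`.
#' @param origin attached origin id.
#' @param facilities non-empty character vector of attached facility ids.
#' @return list with `facility` (id) and `minutes`.
#' @export
closest_facility <- function(network, origin, facilities) {
  if (length(facilities) == 0) abort_scpath("no facilities supplied")
  facilities <- sort(as.character(facilities))
  t <- travel_time_matrix(network, origin, facilities)[1, ]
  if (all(is.infinite(t))) {
    abort_scpath(sprintf("no facility reachable from origin '%s'", origin))
  }
  i <- which.min(t)  # first minimum = smallest id after sorting
  list(facility = facilities[i], minutes = unname(t[i]))
}

#' Two-stage spatial care path for one origin
#'
#' Stage 1 routes the origin to its closest POCT diagnosis site; stage 2
#' routes that site to the care center. If the care center itself carries
#' POCT (is listed among `poct_sites`) it may serve as the diagnosis site,
#' giving a zero second stage.
#'
#' @param network a `road_network`.
#' @param origin attached origin id.
#' @param poct_sites non-empty character vector of diagnosis site ids.
#' @param care_site id of the care destination.
#' @return one-row data frame: `origin_id, diagnosis_facility_id,
#'   t_diag_min, t_care_min, t_total_min`.
#' @export
spatial_care_path <- function(network, origin, poct_sites, care_site) {
  care_paths(network, origin, poct_sites, care_site)
}

#' Spatial care paths for many origins
#'
#' Vectorized form of [spatial_care_path()]: two travel-time matrix passes
#' (origins x sites, sites x care) instead of per-origin searches.
#'
#' @inheritParams spatial_care_path
#' @param origins character vector of attached origin ids.
#' @return data frame with one row per origin. Unreachable stages yield
#'   `Inf` times rather than an error when `strict = FALSE`.
#' @param strict error on any unreachable stage (default TRUE).
#' @export
care_paths <- function(network, origins, poct_sites, care_site, strict = TRUE) {
  if (length(poct_sites) == 0) abort_scpath("poct_sites must be non-empty")
  origins <- as.character(origins)
  poct_sites <- sort(unique(as.character(poct_sites)))
  m1 <- travel_time_matrix(network, origins, poct_sites)
  m2 <- travel_time_matrix(network, poct_sites, care_site)[, 1]

  pick <- apply(m1, 1, which.min)  # first minimum = smallest facility id
  t_diag <- m1[cbind(seq_along(origins), pick)]
  diag_id <- poct_sites[pick]
  t_care <- unname(m2[pick])

  if (strict) {
    if (any(is.infinite(t_diag))) {
      abort_scpath(sprintf(
        "diagnosis stage unreachable for origin(s): %s",
        paste(origins[is.infinite(t_diag)], collapse = ", ")))
    }
    if (any(is.infinite(t_care))) {
      abort_scpath(sprintf(
        "care stage unreachable from diagnosis site(s): %s",
        paste(unique(diag_id[is.infinite(t_care)]), collapse = ", ")))
    }
  }
  data.frame(
    origin_id = origins,
    diagnosis_facility_id = diag_id,
    t_diag_min = unname(t_diag),
    t_care_min = t_care,
    t_total_min = unname(t_diag) + t_care,
    stringsAsFactors = FALSE
  )
}
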