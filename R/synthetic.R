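# Synthetic study regions with the structure of the real inputs: a connected
# mixed-class road network, populated places typed city/suburb/town/village/
# hamlet with default populations, a facility hierarchy (hospitals, health
# promoting hospitals, one tertiary care center) and a current-POCT roster.

#' Default populations by place type
#'
#' The population estimate assigned to a populated place when none is
#' recorded: city 100000, suburb 100000, town 20000, village 10000,
#' hamlet 200.
#'
#' @return named numeric vector.
#' @export
place_population_defaults <- function() {
  c(city = 100000, suburb = 100000, town = 20000, village = 10000,
    hamlet = 200)
}

#' Default place-type mixture
#'
#' Sampling probabilities proportional to the place-type counts of the
#' study region (1 city, 1 suburb, 5 towns, 1303 villages, 83 hamlets).
#'
#' @return named probability vector summing to 1.
#' @export
place_type_mixture_default <- function() {
  counts <- c(city = 1, suburb = 1, town = 5, village = 1303, hamlet = 83)
  counts / sum(counts)
}

# plausible desk-scale road-class mixture for a rural provincial network
class_mixture_default <- function() {
  c(trunk = 0.03, primary = 0.07, secondary = 0.12, tertiary = 0.18,
    unclassified = 0.25, residential = 0.25, service = 0.05,
    living_street = 0.02, road = 0.03)
}

#' Configuration for a synthetic study region
#'
#' Defaults describe a desk-scale region with the structure of the study
#' inputs: place types in the published mixture with their default
#' populations, road classes with the published speeds, the published
#' facility hierarchy (44 hospitals, 347 health promoting hospitals), 14
#' currently equipped POCT hospitals, and the care center placed at the hospital
#' farthest (by network time) from the population-weighted centroid place —
#' emulating a tertiary destination outside the population core.
#'
#' @param seed integer RNG seed; the whole region is deterministic given it.
#' @param network_kind `"grid"` or `"random_planar"`.
#' @param n_junctions target junction count (default 900).
#' @param spacing_m grid spacing / region scale in meters (default 2000).
#' @param class_mixture named probabilities over road classes.
#' @param n_places number of populated places (default 300, a desk-scale
#'   stand-in for the study region's 1393 places).
#' @param place_type_mixture named probabilities over place types.
#' @param n_hospitals,n_hph hospital and health-promoting-hospital counts
#'   (defaults 44 and 347, the published provincial facility totals).
#' @param n_current_poct number of hospitals currently equipped with POCT
#'   (default 14; a free parameter of the generator, not a published value).
#' @param care_site_rule `"farthest_hospital"` or an explicit facility id.
#' @return a `region_config` list.
#' @export
region_config <- function(seed = 1, network_kind = c("grid", "random_planar"),
                          n_junctions = 900, spacing_m = 2000,
                          class_mixture = class_mixture_default(),
                          n_places = 300,
                          place_type_mixture = place_type_mixture_default(),
                          n_hospitals = 44, n_hph = 347,
                          n_current_poct = 14,
                          care_site_rule = "farthest_hospital") {
  network_kind <- match.arg(network_kind)
  stopifnot(n_junctions > 0, n_places > 0, n_hospitals > 0, n_hph >= 0,
            n_current_poct > 0, spacing_m > 0)
  norm <- function(p) {
    if (any(p < 0)) abort_scpath("mixture probabilities must be >= 0")
    p / sum(p)
  }
  class_mixture <- norm(class_mixture)
  assign_speed(names(class_mixture))  # classes must be known
  place_type_mixture <- norm(place_type_mixture)
  if (!all(names(place_type_mixture) %in% names(place_population_defaults()))) {
    abort_scpath("unknown place type in place_type_mixture")
  }
  structure(list(
    seed = as.integer(seed), network_kind = network_kind,
    n_junctions = n_junctions, spacing_m = spacing_m,
    class_mixture = class_mixture, n_places = n_places,
    place_type_mixture = place_type_mixture,
    n_hospitals = n_hospitals, n_hph = n_hph,
    n_current_poct = n_current_poct, care_site_rule = care_site_rule
  ), class = "region_config")
}

#' Generate a synthetic study region
#'
#' Deterministic under `config$seed`. Produces raw layers — roads (polylines
#' with classes), places (typed, with default populations), facilities
#' (hospitals / health promoting hospitals / exactly one care center) and
#' the current-POCT roster (drawn from hospitals) — ready for
#' [build_region_network()].
#'
#' Facilities are sited at junctions sampled with probability proportional
#' to local place density, echoing the tendency of facilities to cluster
#' near populations; each is offset slightly off-road so connector edges are
#' exercised.
#'
#' @param config a [region_config()].
#' @return an `scp_region`: list with `roads`, `places`, `facilities`,
#'   `current_poct`, `care_site`, `config`.
#' @export
generate_region <- function(config = region_config()) {
  stopifnot(inherits(config, "region_config"))
  n_fac <- config$n_hospitals + config$n_hph
  if (n_fac > config$n_junctions) {
    abort_scpath("more facilities requested than junctions available")
  }
  if (config$n_current_poct > config$n_hospitals - 1) {
    abort_scpath("n_current_poct must leave at least one hospital (the care center) unequipped")
  }
  with_seed(config$seed, {
    net_raw <- switch(config$network_kind,
      grid = grid_roads(config$n_junctions, config$spacing_m,
                        config$class_mixture),
      random_planar = gabriel_roads(config$n_junctions, config$spacing_m,
                                    config$class_mixture)
    )
    jxy <- net_raw$junction_xy
    roads <- net_raw$roads

    # places: random junction + offset (so connectors are needed)
    pj <- sample.int(nrow(jxy), config$n_places, replace = TRUE)
    ang <- stats::runif(config$n_places, 0, 2 * pi)
    rad <- stats::runif(config$n_places, 50, 800)
    ptype <- sample(names(config$place_type_mixture), config$n_places,
                    replace = TRUE, prob = config$place_type_mixture)
    places <- data.frame(
      id = sprintf("P%03d", seq_len(config$n_places)),
      x = jxy[pj, 1] + rad * cos(ang),
      y = jxy[pj, 2] + rad * sin(ang),
      place_type = ptype,
      population = unname(place_population_defaults()[ptype]),
      stringsAsFactors = FALSE
    )

    # facilities at distinct junctions, density-weighted by nearby places
    dens <- vapply(seq_len(nrow(jxy)), function(j) {
      1 + sum((places$x - jxy[j, 1])^2 + (places$y - jxy[j, 2])^2 < 3000^2)
    }, numeric(1))
    fj <- sample.int(nrow(jxy), n_fac, replace = FALSE, prob = dens)
    fang <- stats::runif(n_fac, 0, 2 * pi)
    frad <- stats::runif(n_fac, 20, 300)
    kind <- c(rep("hospital", config$n_hospitals), rep("health_promoting_hospital", config$n_hph))
    fid <- c(sprintf("H%02d", seq_len(config$n_hospitals)),
             sprintf("G%03d", seq_len(config$n_hph)))
    facilities <- data.frame(
      id = fid,
      x = jxy[fj, 1] + frad * cos(fang),
      y = jxy[fj, 2] + frad * sin(fang),
      kind = kind,
      has_poct = FALSE,
      stringsAsFactors = FALSE
    )

    care_site <- pick_care_site(config, roads, places, facilities)
    facilities$kind[facilities$id == care_site] <- "care_center"

    eligible <- facilities$id[facilities$kind == "hospital"]
    current_poct <- sort(sample(eligible, config$n_current_poct))
    facilities$has_poct <- facilities$id %in% current_poct

    structure(list(roads = roads, places = places, facilities = facilities,
                   current_poct = current_poct, care_site = care_site,
                   config = config),
              class = "scp_region")
  })
}

# care center: the hospital with the longest network time from the place
# nearest the population-weighted centroid (or an explicit id)
pick_care_site <- function(config, roads, places, facilities) {
  hosp <- facilities[facilities$kind == "hospital", ]
  if (config$care_site_rule != "farthest_hospital") {
    if (!config$care_site_rule %in% hosp$id) {
      abort_scpath("care_site_rule names an unknown hospital id")
    }
    return(config$care_site_rule)
  }
  cx <- sum(places$population * places$x) / sum(places$population)
  cy <- sum(places$population * places$y) / sum(places$population)
  centroid_place <- places[which.min((places$x - cx)^2 + (places$y - cy)^2), ]
  net <- build_network(roads, tolerance_m = 10)
  net <- connect_point(net, centroid_place$id,
                       c(centroid_place$x, centroid_place$y))
  net <- connect_points(net, hosp)
  t <- travel_time_matrix(net, centroid_place$id, hosp$id)[1, ]
  hosp$id[which.max(t)]
}

#' @export
print.scp_region <- function(x, ...) {
  cat(sprintf(
    "<scp_region> %d roads, %d places, %d facilities (care site %s), %d current POCT\n",
    nrow(x$roads), nrow(x$places), nrow(x$facilities), x$care_site,
    length(x$current_poct)))
  invisible(x)
}

#' Build and attach the travel-time network of a region
#'
#' Builds the road network and attaches every place and facility with
#' connector edges.
#'
#' @param region an `scp_region`.
#' @param tolerance_m snap tolerance in meters (default 10).
#' @return a `road_network` with all layer points attached.
#' @export
build_region_network <- function(region, tolerance_m = 10) {
  net <- build_network(region$roads, tolerance_m = tolerance_m)
  net <- connect_points(net, region$places)
  connect_points(net, region$facilities)
}

# square-lattice road layer (deterministic junction placement)
grid_roads <- function(n_junctions, spacing_m, class_mixture) {
  side <- ceiling(sqrt(n_junctions))
  idx <- expand.grid(i = seq_len(side), j = seq_len(side))
  jxy <- cbind((idx$i - 1) * spacing_m, (idx$j - 1) * spacing_m)
  at <- function(i, j) (j - 1) * side + i
  from <- integer(0); to <- integer(0)
  for (j in seq_len(side)) for (i in seq_len(side - 1)) {
    from <- c(from, at(i, j)); to <- c(to, at(i + 1, j))
  }
  for (j in seq_len(side - 1)) for (i in seq_len(side)) {
    from <- c(from, at(i, j)); to <- c(to, at(i, j + 1))
  }
  classes <- sample(names(class_mixture), length(from), replace = TRUE,
                    prob = class_mixture)
  geom <- lapply(seq_along(from), function(k) {
    rbind(jxy[from[k], ], jxy[to[k], ])
  })
  list(
    junction_xy = jxy,
    roads = roads_frame(sprintf("R%04d", seq_along(from)), classes, geom)
  )
}

# Gabriel graph over random junctions (planar, connected, a subgraph of the
# Delaunay triangulation), randomly thinned while preserving connectivity
gabriel_roads <- function(n_junctions, spacing_m, class_mixture,
                          keep_prob = 0.7) {
  side <- ceiling(sqrt(n_junctions)) * spacing_m
  jxy <- cbind(stats::runif(n_junctions, 0, side),
               stats::runif(n_junctions, 0, side))
  edges <- gabriel_edges(jxy)
  len <- sqrt(rowSums((jxy[edges[, 1], , drop = FALSE] -
                         jxy[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$idx <- seq_len(nrow(edges))
  mst <- igraph::mst(g, weights = len)
  in_mst <- seq_len(nrow(edges)) %in% igraph::E(mst)$idx
  keep <- in_mst | stats::runif(nrow(edges)) < keep_prob
  edges <- edges[keep, , drop = FALSE]
  classes <- sample(names(class_mixture), nrow(edges), replace = TRUE,
                    prob = class_mixture)
  geom <- lapply(seq_len(nrow(edges)), function(k) {
    rbind(jxy[edges[k, 1], ], jxy[edges[k, 2], ])
  })
  list(
    junction_xy = jxy,
    roads = roads_frame(sprintf("R%04d", seq_len(nrow(edges))), classes, geom)
  )
}

# Gabriel condition: edge (i,j) iff no third point lies inside the circle
# with diameter ij. O(n^3) but vectorized over the third point.
gabriel_edges <- function(xy) {
  n <- nrow(xy)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      mid <- (xy[i, ] + xy[j, ]) / 2
      r2 <- sum((xy[i, ] - mid)^2)
      d2 <- (xy[, 1] - mid[1])^2 + (xy[, 2] - mid[2])^2
      d2[c(i, j)] <- Inf
      if (all(d2 >= r2 - 1e-9)) out[[length(out) + 1]] <- c(i, j)
    }
  }
  do.call(rbind, out)
}
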