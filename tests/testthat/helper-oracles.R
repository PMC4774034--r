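# Independent oracles and fixture builders shared across tests.

# Exhaustive shortest-path oracle: enumerate all simple paths between the
# junctions of `a` and `b` by depth-first search over the segment table.
# Deliberately independent of the igraph-backed implementation.
brute_shortest_time <- function(network, a, b) {
  resolve <- function(id) {
    if (id %in% names(network$attachment)) network$attachment[[id]] else id
  }
  src <- resolve(a); dst <- resolve(b)
  if (identical(src, dst)) return(0)
  seg <- network$segments
  best <- Inf
  visit <- function(node, dist, seen) {
    if (dist >= best) return(invisible(NULL))
    if (identical(node, dst)) {
      best <<- dist
      return(invisible(NULL))
    }
    inc <- which(seg$u == node | seg$v == node)
    for (k in inc) {
      nxt <- if (seg$u[k] == node) seg$v[k] else seg$u[k]
      if (nxt %in% seen) next
      visit(nxt, dist + seg$travel_time_min[k], c(seen, nxt))
    }
  }
  visit(src, 0, src)
  best
}

# Brute-force P-median oracle: plain loops over every candidate subset.
brute_pmedian <- function(times, weights, candidates, required, k_total) {
  free <- sort(setdiff(candidates, required))
  k_free <- k_total - length(required)
  sets <- if (k_free == 0) list(character(0)) else
    asplit(utils::combn(free, k_free), 2)
  best <- Inf; best_set <- NULL
  for (sel in sets) {
    chosen <- c(required, sel)
    obj <- 0
    for (i in seq_along(weights)) {
      obj <- obj + weights[i] * min(times[i, chosen])
    }
    if (obj < best - 1e-12) {
      best <- obj
      best_set <- sort(chosen)
    }
  }
  list(chosen = best_set, objective = best)
}

# Random small road network: junctions on random coordinates, random edges
# drawn between them (duplicates removed), mixed classes. May be
# disconnected; oracle comparisons handle Inf.
random_small_network <- function(n_junctions, n_edges, connected = FALSE) {
  xy <- cbind(runif(n_junctions, 0, 10000), runif(n_junctions, 0, 10000))
  pairs <- t(utils::combn(n_junctions, 2))
  if (connected) {
    base <- cbind(seq_len(n_junctions - 1), 2:n_junctions)  # path backbone
    extra <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ,
                   drop = FALSE]
    sel <- unique(rbind(base, extra))
  } else {
    sel <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ,
                 drop = FALSE]
  }
  classes <- sample(setdiff(names(speed_table()), "connector"),
                    nrow(sel), replace = TRUE)
  geom <- lapply(seq_len(nrow(sel)), function(k) {
    rbind(xy[sel[k, 1], ], xy[sel[k, 2], ])
  })
  build_network(roads_frame(sprintf("E%03d", seq_len(nrow(sel))),
                            classes, geom),
                tolerance_m = 0)
}

# Tiny region for fast property tests.
small_region <- function(seed) {
  generate_region(region_config(
    seed = seed, n_junctions = 25, n_places = 10,
    n_hospitals = 4, n_hph = 4, n_current_poct = 2))
}

# A simple straight two-junction network of one trunk mile.
one_mile_network <- function() {
  build_network(roads_frame("M", "trunk",
                            list(rbind(c(0, 0), c(1609.344, 0)))))
}
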