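# Hand-built deterministic fixture regions. Both are constructed from
# explicit coordinate tables (no RNG) so they are byte-identical across runs.

#' Hand-sized region with documented P-median optima
#'
#' A 4x4 grid road network, 12 populated places and 8 candidate facilities,
#' small enough that every P-median problem on it can be enumerated
#' exhaustively. The documented optimal site sets and objectives for
#' k = 1..4 (unconstrained, i.e. the "rearrange" family) were computed by
#' brute-force enumeration over all candidate subsets and are shipped as
#' expected values for solver verification.
#'
#' @return list with `region` (an `scp_region`) and `expected` (per-k list
#'   of `chosen` and `objective`).
#' @export
known_optimum_fixture <- function() {
  spacing <- 3000
  grid_xy <- function(i, j) c((i - 1) * spacing, (j - 1) * spacing)
  side <- 4
  from <- integer(0); to <- integer(0)
  at <- function(i, j) (j - 1) * side + i
  for (j in seq_len(side)) for (i in seq_len(side - 1)) {
    from <- c(from, at(i, j)); to <- c(to, at(i + 1, j))
  }
  for (j in seq_len(side - 1)) for (i in seq_len(side)) {
    from <- c(from, at(i, j)); to <- c(to, at(i, j + 1))
  }
  idx <- expand.grid(i = seq_len(side), j = seq_len(side))
  jxy <- cbind((idx$i - 1) * spacing, (idx$j - 1) * spacing)
  classes <- rep(c("primary", "secondary", "tertiary"),
                 length.out = length(from))
  geom <- lapply(seq_along(from), function(k) rbind(jxy[from[k], ], jxy[to[k], ]))
  roads <- roads_frame(sprintf("R%02d", seq_along(from)), classes, geom)

  places <- data.frame(
    id = sprintf("P%02d", 1:12),
    x = c(200, 3100, 6200, 150, 3050, 9100, 250, 6100, 9050, 3200, 6050, 8900),
    y = c(150, 250, 100, 3200, 3100, 200, 6100, 6200, 3100, 9100, 9050, 6100),
    place_type = c("city", "town", "village", "village", "town", "village",
                   "hamlet", "village", "hamlet", "village", "village",
                   "hamlet"),
    stringsAsFactors = FALSE
  )
  places$population <- unname(place_population_defaults()[places$place_type])

  facilities <- data.frame(
    id = c("CC", "H1", "H2", "H3", "H4", "G1", "G2", "G3"),
    x = c(8950, 100, 6100, 3050, 9000, 150, 6050, 3100),
    y = c(8950, 100, 150, 3150, 3050, 6050, 6100, 9000),
    kind = c("care_center", "hospital", "hospital", "hospital", "hospital",
             rep("health_promoting_hospital", 3)),
    has_poct = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )

  region <- structure(list(
    roads = roads, places = places, facilities = facilities,
    current_poct = c("H1", "H3"), care_site = "CC", config = NULL
  ), class = "scp_region")

  # optima for k = 1..4, required = {}, frozen from exhaustive enumeration
  # (plain-loop brute force over all candidate subsets of the fixture)
  expected <- list(
    `1` = list(chosen = "H1", objective = 623754.2449067144),
    `2` = list(chosen = c("G2", "H1"), objective = 391811.0657999706),
    `3` = list(chosen = c("G2", "H1", "H3"), objective = 299831.9898373585),
    `4` = list(chosen = c("G3", "H1", "H2", "H3"), objective = 219629.7540114648)
  )
  list(region = region, expected = expected)
}

#' Region exhibiting diagnosis backtracking
#'
#' A linear road with the care center at the west end: the only currently
#' equipped POCT hospital lies east of the mid-line place, so stage 1 forces
#' eastbound travel that must then be retraced westward, making the total
#' care-path time strictly exceed the direct origin-to-care time. Placing
#' POCT at the near-side (western) hospital removes the detour.
#'
#' @return an `scp_region`.
#' @export
backtracking_region <- function() {
  xs <- seq(0, 40000, by = 5000)
  geom <- lapply(seq_len(length(xs) - 1), function(k) {
    rbind(c(xs[k], 0), c(xs[k + 1], 0))
  })
  roads <- roads_frame(sprintf("R%02d", seq_along(geom)),
                       rep("trunk", length(geom)), geom)
  places <- data.frame(
    id = c("P_west", "P_mid", "P_east"),
    x = c(2000, 20000, 38000),
    y = c(400, 500, 300),
    place_type = c("village", "town", "village"),
    stringsAsFactors = FALSE
  )
  places$population <- unname(place_population_defaults()[places$place_type])
  facilities <- data.frame(
    id = c("CC", "H_near", "H_east"),
    x = c(0, 15000, 30000),
    y = c(0, 0, 0),
    kind = c("care_center", "hospital", "hospital"),
    has_poct = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(
    roads = roads, places = places, facilities = facilities,
    current_poct = "H_east", care_site = "CC", config = NULL
  ), class = "scp_region")
}
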