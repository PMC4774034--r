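test_that("assign_speed returns the published class speeds and rejects unknowns", {
  expect_equal(assign_speed("trunk"), 65)
  expect_equal(assign_speed("service"), 15)
  expect_equal(assign_speed("connector"), 35)
  expect_equal(assign_speed("Living Street"), 25)  # case/separator normalized
  expect_equal(assign_speed(c("primary", "road")), c(55, 35))
  err <- expect_error(assign_speed("motorway_link"), class = "scpath_config_error")
  expect_match(conditionMessage(err), "motorway_link")
})

test_that("endpoints within the snap tolerance merge into shared junctions", {
  r <- roads_frame(c("A", "B"), c("trunk", "trunk"),
                   list(rbind(c(0, 0), c(100, 0)),
                        rbind(c(105, 0), c(200, 0))))
  snapped <- build_network(r, tolerance_m = 10)
  expect_equal(nrow(snapped$junctions), 3)
  expect_equal(nrow(snapped$segments), 2)
  expect_equal(igraph::count_components(as_igraph(snapped)), 1)

  apart <- build_network(r, tolerance_m = 1)
  expect_equal(nrow(apart$junctions), 4)
  expect_equal(nrow(apart$segments), 2)
  expect_equal(igraph::count_components(as_igraph(apart)), 2)
})

test_that("segment invariants hold: arc length, class speed, travel time", {
  net <- one_mile_network()
  seg <- net$segments
  expect_equal(seg$length_m, 1609.344, tolerance = 1e-6)
  expect_equal(seg$speed_mph, 65)
  expect_equal(seg$travel_time_min, 60 / 65, tolerance = 1e-9)

  reg <- small_region(11)
  rnet <- build_region_network(reg)
  with(rnet$segments, {
    expect_equal(length_m, vapply(geometry, scpath:::polyline_length, numeric(1)),
                 tolerance = 1e-6)
    expect_equal(speed_mph, assign_speed(class))
    expect_equal(travel_time_min, (length_m / 1609.344) / speed_mph * 60,
                 tolerance = 1e-9)
  })
})

test_that("travel time decreases with speed and increases with length", {
  expect_true(travel_time_min(1000, 65) < travel_time_min(1000, 15))
  expect_true(travel_time_min(2000, 45) > travel_time_min(1000, 45))
})

test_that("zero-length polylines are dropped with a warning", {
  r <- roads_frame(c("ok", "null"), c("primary", "primary"),
                   list(rbind(c(0, 0), c(500, 0)),
                        rbind(c(1000, 0), c(1000.5, 0))))
  # the 0.5 m polyline collapses to one junction under a 10 m tolerance
  expect_warning(net <- build_network(r, tolerance_m = 10), "null")
  expect_equal(net$segments$id, "ok")
})

test_that("connect_point splits the target segment and conserves total length", {
  net <- one_mile_network()
  before <- network_length_m(net)
  net2 <- connect_point(net, "pt", c(804.672, 100))
  expect_equal(network_length_m(net2), before + 100, tolerance = 1e-6)
  halves <- net2$segments[net2$segments$class == "trunk", ]
  expect_equal(nrow(halves), 2)
  expect_equal(sort(halves$length_m), c(804.672, 804.672), tolerance = 1e-6)
  conn <- net2$segments[net2$segments$class == "connector", ]
  expect_equal(conn$length_m, 100, tolerance = 1e-6)
  expect_equal(conn$speed_mph, 35)
  expect_true("pt" %in% names(net2$attachment))
})

test_that("a point coincident with a junction attaches without a connector", {
  net <- one_mile_network()
  j1 <- net$junctions[1, ]
  net2 <- connect_point(net, "here", c(j1$x, j1$y))
  expect_equal(nrow(net2$segments), nrow(net$segments))
  expect_equal(unname(net2$attachment[["here"]]), j1$id)
})

test_that("equidistant segments tie-break to the smallest segment id", {
  # two parallel roads, point exactly between them
  r <- roads_frame(c("B_road", "A_road"), c("primary", "primary"),
                   list(rbind(c(0, 200), c(1000, 200)),
                        rbind(c(0, -200), c(1000, -200))))
  net <- build_network(r, tolerance_m = 0)
  net2 <- connect_point(net, "mid", c(500, 0))
  conn <- net2$segments[net2$segments$class == "connector", ]
  foot_j <- setdiff(c(conn$u, conn$v), net2$attachment[["mid"]])
  foot_y <- net2$junctions$y[net2$junctions$id == foot_j]
  expect_equal(foot_y, -200)  # A_road sorts before B_road
})

test_that("build_network is idempotent on its own output", {
  reg <- small_region(5)
  net <- build_network(reg$roads, tolerance_m = 10)
  r2 <- roads_frame(net$segments$id, net$segments$class, net$segments$geometry)
  net2 <- build_network(r2, tolerance_m = 10)
  expect_equal(nrow(net2$junctions), nrow(net$junctions))
  expect_equal(nrow(net2$segments), nrow(net$segments))
  expect_equal(sort(net2$segments$length_m), sort(net$segments$length_m),
               tolerance = 1e-9)
  expect_equal(net2$junctions[order(net2$junctions$x, net2$junctions$y),
                              c("x", "y")],
               net$junctions[order(net$junctions$x, net$junctions$y),
                             c("x", "y")],
               ignore_attr = TRUE)
})

test_that("zero tolerance merges only exactly coincident coordinates", {
  r <- roads_frame(c("A", "B", "C"), rep("primary", 3),
                   list(rbind(c(0, 0), c(100, 0)),
                        rbind(c(100, 0), c(200, 0)),     # exact shared endpoint
                        rbind(c(200, 1e-9), c(300, 0)))) # off by a hair
  net <- build_network(r, tolerance_m = 0)
  expect_equal(nrow(net$junctions), 5)
  expect_equal(igraph::count_components(as_igraph(net)), 2)
})

test_that("connector_report summarizes count, total, mean and max in miles", {
  rep2 <- connector_report(c(1, 3) * 1609.344)
  expect_equal(rep2$count, 2)
  expect_equal(rep2$total_miles, 4)
  expect_equal(rep2$mean_miles, 2)
  expect_equal(rep2$max_miles, 3)
  expect_false(rep2$empty)

  empty <- connector_report(numeric(0))
  expect_true(empty$empty)
  expect_equal(empty$count, 0)
  expect_equal(empty$mean_miles, 0)

  net <- connect_point(one_mile_network(), "pt", c(804.672, 100))
  from_net <- connector_report(net)
  expect_equal(from_net$count, 1)
  expect_equal(from_net$total_miles, 100 / 1609.344, tolerance = 1e-9)
})

test_that("validate_connectivity flags exactly the severed pairs", {
  r <- roads_frame(c("west", "east"), c("primary", "primary"),
                   list(rbind(c(0, 0), c(1000, 0)),
                        rbind(c(5000, 0), c(6000, 0))))
  net <- build_network(r, tolerance_m = 0)
  net <- connect_point(net, "o", c(500, 100))
  net <- connect_point(net, "d", c(5500, 100))
  bad <- validate_connectivity(net, "o", "d")
  expect_equal(nrow(bad), 1)
  expect_equal(bad$origin, "o")

  # joining the components clears the report
  bridge <- roads_frame("bridge", "primary", list(rbind(c(1000, 0), c(5000, 0))))
  joined <- build_network(rbind(r, bridge), tolerance_m = 0)
  joined <- connect_point(joined, "o", c(500, 100))
  joined <- connect_point(joined, "d", c(5500, 100))
  expect_equal(nrow(validate_connectivity(joined, "o", "d")), 0)
})
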