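test_that("shortest_time handles identity, single edges, and symmetry", {
  net <- one_mile_network()
  expect_equal(shortest_time(net, "J1", "J1"), 0)
  expect_equal(shortest_time(net, "J1", "J2"), 60 / 65, tolerance = 1e-12)
  expect_equal(shortest_time(net, "J2", "J1"),
               shortest_time(net, "J1", "J2"))
  expect_error(shortest_time(net, "nope", "J1"), "not attached")
})

test_that("shortest_time matches exhaustive path enumeration on random networks", {
  set.seed(402)
  for (rep in 1:25) {
    net <- random_small_network(sample(4:8, 1), sample(5:12, 1))
    js <- net$junctions$id
    a <- sample(js, 1); b <- sample(js, 1)
    expect_equal(shortest_time(net, a, b), brute_shortest_time(net, a, b))
  }
})

test_that("closest_facility returns the argmin with smallest-id tie-break", {
  # line: F_far at 0, origin at 2000, F_near at 3000
  r <- roads_frame("L", "unclassified", list(rbind(c(0, 0), c(6000, 0))))
  net <- build_network(r)
  net <- connect_point(net, "o", c(2000, 0))
  net <- connect_point(net, "F_far", c(0, 0))
  net <- connect_point(net, "F_near", c(3000, 0))
  got <- closest_facility(net, "o", c("F_far", "F_near"))
  expect_equal(got$facility, "F_near")
  expect_equal(got$minutes, travel_time_min(1000, 25), tolerance = 1e-9)

  # origin coincident with a facility
  net <- connect_point(net, "F_here", c(2000, 0))
  expect_equal(closest_facility(net, "o", c("F_here", "F_near"))$minutes, 0)

  # symmetric tie at 1000 m either side -> smallest id wins
  net <- connect_point(net, "B_f", c(1000, 0))
  net <- connect_point(net, "A_f", c(3000, 0))
  tie <- closest_facility(net, "o", c("B_f", "A_f"))
  expect_equal(tie$facility, "A_f")
  expect_error(closest_facility(net, "o", character(0)), "no facilities")
})

test_that("the care path chains diagnosis and care stages", {
  # origin -- A(POCT) -- care on one line: 10 min to A, 20 more to care
  # unclassified 25 mph: 10 min = 25/60*10 miles
  mile <- 1609.344
  d10 <- 25 / 60 * 10 * mile
  d20 <- 25 / 60 * 20 * mile
  r <- roads_frame("L", "unclassified",
                   list(rbind(c(0, 0), c(d10 + d20 + 100, 0))))
  net <- build_network(r)
  net <- connect_point(net, "o", c(0, 0))
  net <- connect_point(net, "A", c(d10, 0))
  net <- connect_point(net, "care", c(d10 + d20, 0))
  p <- spatial_care_path(net, "o", "A", "care")
  expect_equal(p$t_diag_min, 10, tolerance = 1e-9)
  expect_equal(p$t_care_min, 20, tolerance = 1e-9)
  expect_equal(p$t_total_min, p$t_diag_min + p$t_care_min, tolerance = 1e-9)
  expect_equal(p$diagnosis_facility_id, "A")

  # origin at a POCT site that is also the care site
  p0 <- spatial_care_path(net, "A", "A", "A")
  expect_equal(unlist(p0[c("t_diag_min", "t_care_min", "t_total_min")]),
               c(t_diag_min = 0, t_care_min = 0, t_total_min = 0))
})

test_that("forced nearest-POCT diagnosis can require backtracking past the direct route", {
  br <- backtracking_region()
  net <- build_region_network(br)
  paths <- care_paths(net, br$places$id, br$current_poct, br$care_site)
  direct <- vapply(br$places$id, function(p) shortest_time(net, p, br$care_site),
                   numeric(1))
  expect_true(all(paths$t_total_min >= direct - 1e-9))
  expect_true(any(paths$t_total_min > direct + 1e-9))
  # verify stage arithmetic against the shortest_time oracle
  i <- which(paths$origin_id == "P_mid")
  expect_equal(paths$t_diag_min[i], shortest_time(net, "P_mid", "H_east"),
               tolerance = 1e-9)
  expect_equal(paths$t_care_min[i], shortest_time(net, "H_east", "CC"),
               tolerance = 1e-9)
})

test_that("summaries weight by population and match unweighted under equal weights", {
  paths <- data.frame(origin_id = c("a", "b"),
                      diagnosis_facility_id = "f",
                      t_diag_min = c(10, 30), t_care_min = 0,
                      t_total_min = c(10, 30))
  places <- data.frame(id = c("a", "b"), population = c(3, 1))
  s <- summarize_access(paths, places, weighted = TRUE)
  expect_equal(s$mean_diag_min, 15)  # (3*10 + 1*30) / 4
  u <- summarize_access(paths, weighted = FALSE)
  expect_equal(u$mean_diag_min, 20)

  eq <- places; eq$population <- 7
  expect_equal(summarize_access(paths, eq, weighted = TRUE)$mean_diag_min,
               u$mean_diag_min, tolerance = 1e-9)
  expect_equal(summarize_access(paths, eq, weighted = TRUE)$sd_total_min,
               u$sd_total_min, tolerance = 1e-9)

  single <- summarize_access(paths[1, ], places, weighted = TRUE)
  expect_equal(single$sd_total_min, 0)
})

test_that("infinite routes are excluded with a warning and counted", {
  paths <- data.frame(origin_id = c("a", "b", "c"),
                      diagnosis_facility_id = "f",
                      t_diag_min = c(5, Inf, 15), t_care_min = 0,
                      t_total_min = c(5, Inf, 15))
  expect_warning(s <- summarize_access(paths, weighted = FALSE), "excluded 1")
  expect_equal(s$n_routes, 2)
  expect_equal(s$n_excluded, 1)
  expect_equal(s$mean_total_min, 10)
})

test_that("15-minute histogram uses left-closed right-open bins", {
  h <- histogram_15min(c(0, 14.99, 15))
  expect_equal(h$count, c(2, 1))
  expect_equal(h$bin_start_min, c(0, 15))
  expect_equal(nrow(histogram_15min(numeric(0))), 0)

  set.seed(99)
  t <- runif(1000, 0, 60)
  h2 <- histogram_15min(t)
  expect_equal(sum(h2$count), 1000)
  expect_equal(h2$bin_start_min, c(0, 15, 30, 45))
})

test_that("percent_decrease reproduces published table cells", {
  expect_equal(percent_decrease(49.9, 13.9), 72.1)
  expect_equal(percent_decrease(218.5, 173.7), 20.5)
  expect_equal(percent_decrease(100, 100), 0)
  expect_error(percent_decrease(0, 5), "current > 0")
  expect_error(percent_decrease(-3, 5), "current > 0")
})
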