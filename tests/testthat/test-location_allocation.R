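# shared small problem: demand/candidate times drawn once per case
make_problem <- function(n_demand, candidates, required = character(0),
                         k_total, weights = NULL) {
  times <- matrix(runif(n_demand * length(candidates), 1, 60),
                  nrow = n_demand,
                  dimnames = list(sprintf("d%02d", seq_len(n_demand)),
                                  candidates))
  demand <- data.frame(id = rownames(times),
                       weight = weights %||% runif(n_demand, 1, 100))
  pmedian_problem(demand, candidates, required, k_total, times)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("problem construction validates constraints", {
  expect_error(make_problem(3, c("f1", "f2"), required = "f9", k_total = 1),
               "subset of candidates")
  expect_error(make_problem(3, c("f1", "f2"), required = c("f1", "f2"),
                            k_total = 1), "smaller than the required")
  expect_error(make_problem(3, c("f1", "f2"), k_total = 3),
               "exceeds the number of candidates")
})

test_that("exact solver: saturation and single-demand base cases", {
  set.seed(21)
  pr <- make_problem(6, sprintf("f%d", 1:5), k_total = 5)
  sol <- solve_exact(pr)
  expect_equal(sol$chosen, sort(pr$candidates))
  expect_equal(sol$objective,
               sum(pr$demand$weight * apply(pr$times, 1, min)),
               tolerance = 1e-12)

  pr1 <- make_problem(1, sprintf("f%d", 1:4), k_total = 1)
  sol1 <- solve_exact(pr1)
  expect_equal(sol1$chosen, colnames(pr1$times)[which.min(pr1$times[1, ])])
})

test_that("exact solver matches plain-loop enumeration on random problems", {
  set.seed(31)
  for (rep in 1:10) {
    pr <- make_problem(8, sprintf("f%d", 1:8), k_total = 3)
    sol <- solve_exact(pr)
    oracle <- brute_pmedian(pr$times, pr$demand$weight, pr$candidates,
                            pr$required, pr$k_total)
    expect_equal(sol$objective, oracle$objective, tolerance = 1e-9)
    expect_equal(sol$chosen, oracle$chosen)
  }
})

test_that("enumeration cap triggers an informative error", {
  set.seed(5)
  pr <- make_problem(4, sprintf("f%02d", 1:20), k_total = 10)
  expect_error(solve_exact(pr, cap = 100), "solve_heuristic")
})

test_that("heuristic is bounded below by the exact optimum and attains it on the fixture", {
  set.seed(41)
  for (rep in 1:10) {
    pr <- make_problem(10, sprintf("f%d", 1:9), k_total = sample(2:4, 1))
    he <- solve_heuristic(pr, seed = rep)
    ex <- solve_exact(pr)
    expect_gte(he$objective, ex$objective - 1e-9)
  }

  fx <- known_optimum_fixture()
  net <- build_region_network(fx$region)
  cand <- sort(fx$region$facilities$id)
  times <- travel_time_matrix(net, fx$region$places$id, cand)
  demand <- data.frame(id = fx$region$places$id,
                       weight = fx$region$places$population)
  for (k in 1:4) {
    pr <- pmedian_problem(demand, cand, character(0), k, times)
    expected <- fx$expected[[as.character(k)]]
    ex <- solve_exact(pr)
    he <- solve_heuristic(pr, seed = 1)
    expect_equal(ex$objective, expected$objective, tolerance = 1e-9)
    expect_equal(ex$chosen, sort(expected$chosen))
    expect_equal(he$objective, expected$objective, tolerance = 1e-9)
  }
})

test_that("required budget exhausted means no search: chosen = required", {
  set.seed(8)
  pr <- make_problem(5, sprintf("f%d", 1:6), required = c("f2", "f5"),
                     k_total = 2)
  for (sol in list(solve_exact(pr), solve_heuristic(pr))) {
    expect_equal(sol$chosen, c("f2", "f5"))
  }
})

test_that("heuristic is deterministic for a fixed seed", {
  set.seed(77)
  pr <- make_problem(12, sprintf("f%d", 1:10), k_total = 4)
  a <- solve_heuristic(pr, seed = 42)
  b <- solve_heuristic(pr, seed = 42)
  expect_identical(a$chosen, b$chosen)
  expect_identical(a$objective, b$objective)
})

test_that("objective is monotone in budget and relaxing constraints never hurts", {
  set.seed(55)
  for (rep in 1:5) {
    cand <- sprintf("f%d", 1:8)
    pr_base <- make_problem(8, cand, k_total = 2)
    objs <- vapply(2:5, function(k) {
      solve_exact(pmedian_problem(pr_base$demand, cand, character(0), k,
                                  pr_base$times))$objective
    }, numeric(1))
    expect_true(all(diff(objs) <= 1e-9))

    existing <- sample(cand, 3)
    keep <- build_strategy("keep_plus_k", existing, 2, cand, pr_base$demand,
                           pr_base$times)
    rearr <- build_strategy("rearrange_plus_k", existing, 2, cand,
                            pr_base$demand, pr_base$times)
    expect_lte(solve_exact(rearr)$objective, solve_exact(keep)$objective + 1e-9)
  }
})

test_that("strategy construction maps to the right constraints", {
  set.seed(2)
  cand <- sprintf("f%02d", 1:20)
  pr0 <- make_problem(5, cand, k_total = 1)
  existing <- sprintf("f%02d", 1:14)

  re <- build_strategy("rearrange", existing, candidates = cand,
                       demand = pr0$demand, times = pr0$times)
  expect_equal(re$k_total, 14L)
  expect_equal(re$required, character(0))

  k5 <- build_strategy("keep_plus_k", existing, 5, cand, pr0$demand, pr0$times)
  expect_equal(k5$required, sort(existing))
  expect_error(build_strategy("keep_plus_k", existing, 5,
                              candidates = existing,
                              demand = pr0$demand, times = pr0$times),
               "exceeds")

  r10 <- build_strategy("rearrange_plus_k", existing[1:2], 10, cand,
                        pr0$demand, pr0$times)
  expect_equal(r10$required, character(0))
  expect_equal(r10$k_total, 12L)
})

test_that("stored assignments re-derive as each place's nearest chosen site", {
  set.seed(64)
  pr <- make_problem(9, sprintf("f%d", 1:7), required = "f3", k_total = 3)
  sol <- solve_heuristic(pr, seed = 3)
  expect_true(all(pr$required %in% sol$chosen))
  for (i in seq_len(nrow(pr$times))) {
    row <- pr$times[i, sol$chosen]
    nearest <- sol$chosen[which.min(row)]
    expect_equal(sol$assignment$facility_id[i], nearest)
    expect_equal(sol$assignment$t_min[i], min(row))
  }
  expect_equal(sol$objective,
               sum(pr$demand$weight * sol$assignment$t_min),
               tolerance = 1e-12)
})
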