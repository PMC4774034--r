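# Constrained P-median facility selection: choose k_total sites (a required
# subset forced in) minimizing the demand-weighted sum of travel times from
# each demand point to its nearest chosen site.

#' Construct a P-median problem
#'
#' @param demand data frame with columns `id` and `weight` (>= 0), one row
#'   per demand point (typically populated places weighted by population).
#' @param candidates character vector of candidate facility ids.
#' @param required subset of `candidates` that must be selected.
#' @param k_total total number of sites to select (>= `length(required)`).
#' @param times numeric matrix of minutes, rows named by demand ids and
#'   columns by candidate ids (see [travel_time_matrix()]).
#' @return a `pmedian_problem`.
#' @export
pmedian_problem <- function(demand, candidates, required = character(0),
                            k_total, times) {
  candidates <- sort(unique(as.character(candidates)))
  required <- sort(unique(as.character(required)))
  if (!all(required %in% candidates)) {
    abort_scpath("required sites must be a subset of candidates")
  }
  if (k_total < length(required)) {
    abort_scpath("k_total is smaller than the required set")
  }
  if (k_total > length(candidates)) {
    abort_scpath("k_total exceeds the number of candidates")
  }
  stopifnot(is.data.frame(demand), all(c("id", "weight") %in% names(demand)),
            all(demand$weight >= 0))
  if (!all(demand$id %in% rownames(times)) ||
      !all(candidates %in% colnames(times))) {
    abort_scpath("times matrix must cover every demand row and candidate column")
  }
  times <- times[as.character(demand$id), candidates, drop = FALSE]
  structure(list(demand = demand, candidates = candidates, required = required,
                 k_total = as.integer(k_total), times = times),
            class = "pmedian_problem")
}

# row-wise minimum over a column subset (column pmin: much faster than apply)
rowmin_cols <- function(times, cols) {
  Reduce(pmin, lapply(cols, function(cc) times[, cc]))
}

# demand-weighted objective of a chosen site set
pm_objective <- function(problem, chosen) {
  sum(problem$demand$weight * rowmin_cols(problem$times, chosen))
}

# assign each demand point to its nearest chosen site (ties: smallest id)
pm_assign <- function(problem, chosen) {
  chosen <- sort(chosen)
  m <- problem$times[, chosen, drop = FALSE]
  pick <- apply(m, 1, which.min)
  data.frame(
    place_id = as.character(problem$demand$id),
    facility_id = chosen[pick],
    t_min = m[cbind(seq_len(nrow(m)), pick)],
    stringsAsFactors = FALSE
  )
}

new_pmedian_solution <- function(problem, chosen, method) {
  chosen <- sort(chosen)
  assignment <- pm_assign(problem, chosen)
  structure(list(
    chosen = chosen,
    objective = sum(problem$demand$weight * assignment$t_min),
    assignment = assignment,
    method = method
  ), class = "pmedian_solution")
}

#' @export
print.pmedian_solution <- function(x, ...) {
  cat(sprintf("<pmedian_solution> %d sites (%s), objective %.2f weighted min\n",
              length(x$chosen), x$method, x$objective))
  invisible(x)
}

#' Exact P-median solution by exhaustive enumeration
#'
#' Enumerates every feasible site set (required sites forced in) and returns
#' the global optimum. Among ties the lexicographically smallest chosen set
#' wins. Intended as the oracle for small problems; the number of free
#' combinations must not exceed `cap`.
#'
#' @param problem a [pmedian_problem()].
#' @param cap maximum number of candidate subsets to enumerate
#'   (default 200000).
#' @return a `pmedian_solution` with `chosen`, `objective`, `assignment`.
#' @export
solve_exact <- function(problem, cap = 200000) {
  stopifnot(inherits(problem, "pmedian_problem"))
  free <- setdiff(problem$candidates, problem$required)
  k_free <- problem$k_total - length(problem$required)
  n_comb <- choose(length(free), k_free)
  if (n_comb > cap) {
    abort_scpath(sprintf(
      "exact enumeration needs %.0f subsets (> cap %d); use solve_heuristic",
      n_comb, cap))
  }
  w <- problem$demand$weight
  base <- if (length(problem$required) > 0) {
    rowmin_cols(problem$times, problem$required)
  } else {
    rep(Inf, nrow(problem$times))
  }
  best_obj <- Inf
  best <- NULL
  if (k_free == 0) {
    best <- problem$required
    best_obj <- sum(w * base)
  } else {
    combos <- utils::combn(free, k_free)  # lexicographic over sorted free ids
    for (j in seq_len(ncol(combos))) {
      sel <- combos[, j]
      t_min <- pmin(base, rowmin_cols(problem$times, sel))
      obj <- sum(w * t_min)
      if (obj < best_obj - 1e-12) {  # strict: first optimum = lexicographically smallest
        best_obj <- obj
        best <- c(problem$required, sel)
      }
    }
  }
  new_pmedian_solution(problem, best, method = "exact")
}

#' Heuristic P-median solution (greedy + vertex substitution)
#'
#' Greedy addition from the required set, then Teitz-Bart style local search:
#' repeatedly apply the best strictly improving single swap of a chosen free
#' site for an unchosen candidate, until none exists. The search restarts
#' `n_restarts` times (first start greedy, later starts random) and keeps the
#' best solution; deterministic for a given `seed`. The heuristic objective
#' is always an upper bound on the exact optimum.
#'
#' @param problem a [pmedian_problem()].
#' @param seed RNG seed for the random restarts.
#' @param n_restarts number of starts (default 5).
#' @return a `pmedian_solution`.
#' @export
solve_heuristic <- function(problem, seed = 1, n_restarts = 5) {
  stopifnot(inherits(problem, "pmedian_problem"))
  free <- setdiff(problem$candidates, problem$required)
  k_free <- problem$k_total - length(problem$required)
  if (k_free == 0) {
    return(new_pmedian_solution(problem, problem$required, method = "heuristic"))
  }
  times <- problem$times
  w <- problem$demand$weight
  greedy_start <- function() {
    sel <- character(0)
    cur_min <- if (length(problem$required) > 0) {
      rowmin_cols(times, problem$required)
    } else {
      rep(Inf, nrow(times))
    }
    while (length(sel) < k_free) {
      rest <- setdiff(free, sel)  # sorted: ties resolve to smallest id
      objs <- vapply(rest, function(f) sum(w * pmin(cur_min, times[, f])),
                     numeric(1))
      add <- rest[which.min(objs)]
      cur_min <- pmin(cur_min, times[, add])
      sel <- c(sel, add)
    }
    sel
  }
  # Teitz-Bart swap search with best/second-best bookkeeping: removing a
  # chosen site falls back to each row's second-nearest chosen site
  local_search <- function(sel) {
    repeat {
      chosen <- c(problem$required, sort(sel))
      m <- times[, chosen, drop = FALSE]
      rows <- seq_len(nrow(m))
      arg1 <- max.col(-m, ties.method = "first")
      best1 <- m[cbind(rows, arg1)]
      m2 <- m; m2[cbind(rows, arg1)] <- Inf
      best2 <- m2[cbind(rows, max.col(-m2, ties.method = "first"))]
      cur <- sum(w * best1)
      best_gain <- 0
      best_swap <- NULL
      ins <- sort(setdiff(free, sel))
      for (o in sort(sel)) {
        pos <- match(o, chosen)
        without_o <- ifelse(arg1 == pos, best2, best1)
        for (i in ins) {
          obj <- sum(w * pmin(without_o, times[, i]))
          gain <- cur - obj
          if (gain > best_gain + 1e-12) {
            best_gain <- gain
            best_swap <- c(o, i)
          }
        }
      }
      if (is.null(best_swap)) return(sel)
      sel <- c(setdiff(sel, best_swap[1]), best_swap[2])
    }
  }
  starts <- with_seed(seed, {
    s <- list(greedy_start())
    if (n_restarts > 1) {
      for (r in seq_len(n_restarts - 1)) {
        s <- c(s, list(sample(free, k_free)))
      }
    }
    s
  })
  best <- NULL
  best_obj <- Inf
  for (s in starts) {
    sel <- local_search(s)
    obj <- pm_objective(problem, c(problem$required, sel))
    full <- sort(c(problem$required, sel))
    if (obj < best_obj - 1e-12 ||
        (abs(obj - best_obj) <= 1e-12 &&
         paste(full, collapse = "\r") < paste(sort(best), collapse = "\r"))) {
      best_obj <- obj
      best <- full
    }
  }
  new_pmedian_solution(problem, best, method = "heuristic")
}

#' Build a limited-resource POCT placement problem
#'
#' Translates the three deployment strategies into P-median constraints:
#' \describe{
#'   \item{rearrange}{relocate the existing POCT freely: no required sites,
#'     budget equal to the current count.}
#'   \item{keep_plus_k}{keep existing POCT in place and add `k_extra` more:
#'     required = existing, budget = existing + k_extra.}
#'   \item{rearrange_plus_k}{add `k_extra` and relocate everything: no
#'     required sites, budget = existing + k_extra.}
#' }
#'
#' @param strategy one of `"rearrange"`, `"keep_plus_k"`,
#'   `"rearrange_plus_k"`.
#' @param existing_poct character vector of currently equipped facility ids
#'   (must be candidates).
#' @param k_extra number of additional POCT units (ignored for
#'   `"rearrange"`).
#' @param candidates,demand,times as in [pmedian_problem()].
#' @return a `pmedian_problem`.
#' @export
build_strategy <- function(strategy = c("rearrange", "keep_plus_k",
                                        "rearrange_plus_k"),
                           existing_poct, k_extra = 0, candidates, demand,
                           times) {
  strategy <- match.arg(strategy)
  existing_poct <- as.character(existing_poct)
  if (!all(existing_poct %in% candidates)) {
    abort_scpath("existing POCT sites must be candidates")
  }
  n0 <- length(unique(existing_poct))
  spec <- switch(strategy,
    rearrange        = list(required = character(0), k_total = n0),
    keep_plus_k      = list(required = existing_poct, k_total = n0 + k_extra),
    rearrange_plus_k = list(required = character(0), k_total = n0 + k_extra)
  )
  pmedian_problem(demand, candidates, spec$required, spec$k_total, times)
}
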