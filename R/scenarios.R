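# Named deployment scenarios: current access, widespread POCT adoption
# (all hospitals / all facilities), and limited-resource strategies whose
# site sets come from the P-median solver.

#' Define a POCT deployment scenario
#'
#' @param name scenario label used in comparison tables.
#' @param care_site facility id of the single care destination.
#' @param poct_sites explicit character vector of diagnosis site ids
#'   (required when `rule = "explicit"`).
#' @param rule `"explicit"`, `"all_hospitals"` (every facility of kind
#'   hospital) or `"all_facilities"` (every facility).
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(name, care_site, poct_sites = NULL,
                          rule = c("explicit", "all_hospitals",
                                   "all_facilities")) {
  rule <- match.arg(rule)
  if (rule == "explicit" && length(poct_sites) == 0) {
    abort_scpath("explicit scenario needs a non-empty poct_sites set")
  }
  structure(list(name = name, care_site = as.character(care_site),
                 poct_sites = as.character(poct_sites %||% character(0)),
                 rule = rule),
            class = "scenario_spec")
}

#' Expand a scenario rule into a concrete site set
#'
#' The care center is always included as a permissible diagnosis site: a
#' patient who reaches the tertiary hospital is diagnosed there rather than
#' being routed back out.
#'
#' @param spec a [scenario_spec()].
#' @param facilities data frame with columns `id`, `kind` (kinds `hospital`,
#'   `health_promoting_hospital`, `care_center`).
#' @return sorted character vector of diagnosis site ids.
#' @export
expand_scenario <- function(spec, facilities) {
  stopifnot(inherits(spec, "scenario_spec"))
  sites <- switch(spec$rule,
    explicit = spec$poct_sites,
    all_hospitals = facilities$id[facilities$kind %in%
                                    c("hospital", "care_center")],
    all_facilities = facilities$id
  )
  sites <- sort(unique(c(as.character(sites), spec$care_site)))
  if (length(sites) == 0) abort_scpath("scenario expands to an empty site set")
  miss <- setdiff(sites, facilities$id)
  if (length(miss) > 0) {
    abort_scpath(sprintf("scenario site(s) not in the facility roster: %s",
                         paste(miss, collapse = ", ")))
  }
  sites
}

#' Run one scenario: care paths + access summary
#'
#' @param network a `road_network` with places and facilities attached.
#' @param places data frame `id, x, y, place_type, population`.
#' @param facilities data frame `id, x, y, kind, has_poct`.
#' @param spec a [scenario_spec()].
#' @param weighted population-weight the summary (default TRUE).
#' @return an `access_summary` with the scenario name attached
#'   (`$name`), plus `$paths` holding the per-origin care paths.
#' @export
run_scenario <- function(network, places, facilities, spec, weighted = TRUE) {
  sites <- expand_scenario(spec, facilities)
  paths <- care_paths(network, places$id, sites, spec$care_site)
  s <- summarize_access(paths, places, weighted = weighted)
  s$name <- spec$name
  s$paths <- paths
  s
}

#' Compare scenarios against a baseline
#'
#' Builds a comparison table in the shape of published access tables: one
#' row per scenario with stage means/SDs and percent decreases relative to
#' the baseline, computed from unrounded means then rounded to 1 decimal.
#' The baseline row's percent columns are `NA` (printed "N/A").
#'
#' @param baseline an `access_summary` (the current-access row).
#' @param others list of `access_summary` objects.
#' @return data frame, one row per scenario starting with the baseline.
#' @export
compare_scenarios <- function(baseline, others) {
  if (!is.null(baseline$paths)) {
    roster <- sort(baseline$paths$origin_id)
    for (s in others) {
      if (!is.null(s$paths) && !identical(sort(s$paths$origin_id), roster)) {
        abort_scpath(sprintf(
          "scenario '%s' covers a different place roster than the baseline",
          s$name %||% "?"))
      }
    }
  }
  row <- function(s, base = NULL) {
    data.frame(
      scenario = s$name %||% "scenario",
      mean_diag_min = s$mean_diag_min, sd_diag_min = s$sd_diag_min,
      pct_decrease_diag = if (is.null(base)) NA_real_ else
        percent_decrease(base$mean_diag_min, s$mean_diag_min),
      mean_care_min = s$mean_care_min, sd_care_min = s$sd_care_min,
      pct_decrease_care = if (is.null(base)) NA_real_ else
        percent_decrease(base$mean_care_min, s$mean_care_min),
      mean_total_min = s$mean_total_min, sd_total_min = s$sd_total_min,
      pct_decrease_total = if (is.null(base)) NA_real_ else
        percent_decrease(base$mean_total_min, s$mean_total_min),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(list(row(baseline)),
                   lapply(others, row, base = baseline)))
}

#' Optimize POCT placement for a limited-resource strategy
#'
#' Precomputes the demand-by-candidate travel-time matrix, builds the
#' strategy's constrained P-median problem and solves it. The objective
#' minimizes stage-1 (to-diagnosis) time by default; `objective = "total"`
#' instead minimizes time to diagnosis plus onward time to care.
#'
#' @param network a `road_network` with places and facilities attached.
#' @param places,facilities layer data frames (see [run_scenario()]).
#' @param strategy,k_extra see [build_strategy()].
#' @param current_poct character vector of currently equipped facility ids.
#' @param care_site care destination facility id.
#' @param objective `"diagnosis"` (default) or `"total"`.
#' @param method `"auto"` (exact when enumerable, else heuristic),
#'   `"exact"`, or `"heuristic"`.
#' @param seed,n_restarts heuristic controls.
#' @param cap enumeration cap for the exact solver in auto mode.
#' @return list with `solution` (a `pmedian_solution`), `sites` (chosen ids
#'   including the care site) and `problem`.
#' @export
optimize_poct <- function(network, places, facilities, strategy, k_extra = 0,
                          current_poct, care_site,
                          objective = c("diagnosis", "total"),
                          method = c("auto", "exact", "heuristic"),
                          seed = 1, n_restarts = 5, cap = 200000) {
  objective <- match.arg(objective)
  method <- match.arg(method)
  candidates <- sort(unique(facilities$id))
  times <- travel_time_matrix(network, places$id, candidates)
  if (objective == "total") {
    onward <- travel_time_matrix(network, candidates, care_site)[, 1]
    times <- sweep(times, 2, onward[colnames(times)], `+`)
  }
  demand <- data.frame(id = as.character(places$id),
                       weight = places$population, stringsAsFactors = FALSE)
  problem <- build_strategy(strategy, current_poct, k_extra, candidates,
                            demand, times)
  free <- length(problem$candidates) - length(problem$required)
  k_free <- problem$k_total - length(problem$required)
  use_exact <- switch(method,
    exact = TRUE,
    heuristic = FALSE,
    auto = choose(free, k_free) <= cap
  )
  solution <- if (use_exact) solve_exact(problem, cap = cap) else
    solve_heuristic(problem, seed = seed, n_restarts = n_restarts)
  list(solution = solution,
       sites = sort(unique(c(solution$chosen, as.character(care_site)))),
       problem = problem)
}
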