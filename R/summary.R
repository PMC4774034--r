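#' Population-weighted access summary
#'
#' Summarizes a set of care-path results into mean and SD travel times for
#' the diagnosis stage, the care stage and the total, optionally weighted by
#' place population (frequency weights: a place of population w counts as w
#' identical travellers). With all populations equal the weighted and
#' unweighted summaries coincide. Routes with infinite travel time are
#' excluded with a warning and `n_routes` reflects the exclusion.
#'
#' Weighted mean: sum(w t) / sum(w). The weighted SD normalizes the weights
#' to mean 1 and uses the sample form
#' sqrt(sum(w' (t - m)^2) / (n - 1)) with w' = n w / sum(w), so that any
#' set of equal weights reduces exactly to the ordinary sample SD.
#' A single route reports SD 0.
#'
#' @param paths data frame from [care_paths()].
#' @param places data frame with columns `id`, `population`; required when
#'   `weighted = TRUE`.
#' @param weighted population-weight the summary? (default TRUE)
#' @return an `access_summary`: list with `n_routes`, `n_excluded`,
#'   `mean_diag_min`, `sd_diag_min`, `mean_care_min`, `sd_care_min`,
#'   `mean_total_min`, `sd_total_min`, `weighted`, `histogram_15min`.
#' @export
summarize_access <- function(paths, places = NULL, weighted = TRUE) {
  stopifnot(is.data.frame(paths))
  if (weighted) {
    if (is.null(places)) abort_scpath("weighted summary requires `places`")
    w <- places$population[match(paths$origin_id, places$id)]
    if (anyNA(w)) {
      abort_scpath(sprintf("no population for origin(s): %s",
        paste(paths$origin_id[is.na(w)], collapse = ", ")))
    }
  } else {
    w <- rep(1, nrow(paths))
  }
  finite <- is.finite(paths$t_total_min)
  n_excl <- sum(!finite)
  if (n_excl > 0) {
    warning(sprintf("excluded %d route(s) with infinite travel time", n_excl))
    paths <- paths[finite, ]
    w <- w[finite]
  }
  wstat <- function(t) {
    if (length(t) == 0) return(c(mean = NA_real_, sd = NA_real_))
    n <- length(t)
    m <- sum(w * t) / sum(w)
    wn <- n * w / sum(w)  # mean-1 normalization
    s <- if (n < 2) 0 else sqrt(sum(wn * (t - m)^2) / (n - 1))
    c(mean = m, sd = s)
  }
  d <- wstat(paths$t_diag_min)
  cc <- wstat(paths$t_care_min)
  tt <- wstat(paths$t_total_min)
  structure(list(
    n_routes = nrow(paths), n_excluded = n_excl,
    mean_diag_min = d[["mean"]], sd_diag_min = d[["sd"]],
    mean_care_min = cc[["mean"]], sd_care_min = cc[["sd"]],
    mean_total_min = tt[["mean"]], sd_total_min = tt[["sd"]],
    weighted = weighted,
    histogram_15min = histogram_15min(paths)
  ), class = "access_summary")
}

#' @export
print.access_summary <- function(x, ...) {
  cat(sprintf(
    "<access_summary> n=%d%s (%s)\n  to diagnosis %.1f (%.1f) min\n  to care      %.1f (%.1f) min\n  total        %.1f (%.1f) min\n",
    x$n_routes,
    if (x$n_excluded > 0) sprintf(" (+%d excluded)", x$n_excluded) else "",
    if (x$weighted) "population-weighted" else "unweighted",
    x$mean_diag_min, x$sd_diag_min, x$mean_care_min, x$sd_care_min,
    x$mean_total_min, x$sd_total_min))
  invisible(x)
}

#' Travel-time histogram in 15-minute bins
#'
#' Bins total travel time into left-closed, right-open 15-minute intervals
#' `[0,15), [15,30), ...`; counts sum to the number of routes.
#'
#' @param paths data frame with a `t_total_min` column, or a numeric vector
#'   of times in minutes (finite, >= 0).
#' @return data frame `bin_start_min, count`; zero rows for empty input.
#' @export
histogram_15min <- function(paths) {
  t <- if (is.data.frame(paths)) paths$t_total_min else as.numeric(paths)
  t <- t[is.finite(t)]
  if (length(t) == 0) {
    return(data.frame(bin_start_min = numeric(0), count = integer(0)))
  }
  bin <- floor(t / 15)
  counts <- tabulate(bin + 1, nbins = max(bin) + 1)
  data.frame(bin_start_min = 15 * (seq_along(counts) - 1), count = counts)
}

#' Percent decrease relative to a baseline
#'
#' `100 * (current - alternative) / current`, rounded to one decimal for
#' parity with published comparison tables.
#'
#' @param current baseline value(s), must be > 0 (minutes or percent —
#'   any consistent unit).
#' @param alternative comparison value(s) in the same units.
#' @param digits decimals to round to (default 1); `NULL` for no rounding.
#' @return percent decrease (negative when the alternative is worse).
#' @export
#' @examples
#' percent_decrease(49.9, 13.9)   # 72.1
#' percent_decrease(218.5, 173.7) # 20.5
percent_decrease <- function(current, alternative, digits = 1) {
  if (any(current <= 0)) abort_scpath("percent_decrease requires current > 0")
  out <- 100 * (current - alternative) / current
  if (!is.null(digits)) out <- round(out, digits)
  out
}
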