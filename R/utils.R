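# meters per statute mile; all internal lengths are meters, times minutes
METERS_PER_MILE <- 1609.344

#' Travel time of a road segment
#'
#' Converts a segment length in meters and a speed in miles per hour into
#' minutes of travel: `(length_m / 1609.344) / speed_mph * 60`.
#'
#' @param length_m segment length in meters (>= 0).
#' @param speed_mph travel speed in miles per hour (> 0).
#' @return travel time in minutes.
#' @export
travel_time_min <- function(length_m, speed_mph) {
  stopifnot(all(speed_mph > 0))
  (length_m / METERS_PER_MILE) / speed_mph * 60
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_scpath <- function(msg, class = "scpath_error") {
  stop(errorCondition(msg, class = c(class, "scpath_error")))
}
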