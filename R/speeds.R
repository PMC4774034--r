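#' Road-class travel speeds
#'
#' The estimated travel speed, in miles per hour, assigned to each
#' OpenStreetMap highway class used in the analysis. `connector` is the
#' class given to the synthetic straight-line edges that join off-network
#' points (populated places, health facilities) to the nearest road.
#'
#' @return named numeric vector of speeds in mph, one per supported
#'   highway class.
#' @export
#' @examples
#' speed_table()[["trunk"]]
speed_table <- function() {
  c(
    trunk         = 65,
    primary       = 55,
    secondary     = 45,
    tertiary      = 30,
    unclassified  = 25,
    residential   = 25,
    service       = 15,
    living_street = 25,
    road          = 35,
    connector     = 35
  )
}

#' Speed for a highway class
#'
#' Looks up the estimated travel speed for a road class. Class labels are
#' case-normalized and may use a space or hyphen in place of the underscore
#' (`"Living Street"` == `"living_street"`). Unknown classes are an error so
#' that data problems surface early instead of being silently defaulted.
#'
#' @param highway_class character vector of road class labels.
#' @param speeds speed lookup, as returned by [speed_table()]; may be
#'   overridden to run sensitivity analyses.
#' @return numeric vector of speeds in mph.
#' @export
#' @examples
#' assign_speed("trunk")     # 65
#' assign_speed("connector") # 35
assign_speed <- function(highway_class, speeds = speed_table()) {
  key <- normalize_class(highway_class)
  unknown <- setdiff(unique(key), names(speeds))
  if (length(unknown) > 0) {
    abort_scpath(
      sprintf("unknown road class label(s): %s", paste(unknown, collapse = ", ")),
      class = "scpath_config_error"
    )
  }
  unname(speeds[key])
}

normalize_class <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(as.character(x))))
}
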