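#' @title Gridded field serialisation
#'
#' @description
#' Fields are stored in a CF-style plain-text (JSON) container that mirrors
#' the layout of a gridded NetCDF file: dimension vectors `time`, `lat`,
#' `lon` (separate atmosphere and ocean time axes), one entry per variable
#' (`sat`, `u10`, `v10`, `ssrd`, `uo`, `vo`) carrying a `units` attribute and
#' a flattened data payload in (time, lat, lon) order. A plain-text carrier
#' keeps the on-disk artifact portable and diff-able; values round-trip at
#' full double precision.
#'
#' @name env_io
NULL

.ENV_VARS <- c(sat = "degC", u10 = "m s-1", v10 = "m s-1",
               ssrd = "W m-2", uo = "m s-1", vo = "m s-1")

#' Write an environmental field set to disk
#'
#' @param fieldset an `env_fieldset` from [generate_fields()] or
#'   [read_fields()].
#' @param path output file path (conventionally `.envjson`).
#' @return `path`, invisibly.
#' @export
write_fields <- function(fieldset, path) {
  stopifnot(inherits(fieldset, "env_fieldset"))
  vars <- lapply(names(.ENV_VARS), function(v) {
    time_axis <- if (v %in% c("uo", "vo")) "time_ocean" else "time_atmos"
    list(dims = c(time_axis, "lat", "lon"),
         units = unname(.ENV_VARS[[v]]),
         data = as.vector(fieldset[[v]]))
  })
  names(vars) <- names(.ENV_VARS)
  obj <- list(
    conventions = "CF-like gridded JSON v1",
    dimensions = list(lat = fieldset$lat, lon = fieldset$lon,
                      time_atmos = fieldset$time_atmos,
                      time_ocean = fieldset$time_ocean),
    dimension_units = list(lat = "degrees_north", lon = "degrees_east",
                           time_atmos = "hours since year-1 day-1 00:00",
                           time_ocean = "hours since year-1 day-1 00:00"),
    variables = vars)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an environmental field set from disk
#'
#' Validates the container layout and raises a format error naming any
#' missing variable or dimension. A `sat` variable stored with units `"K"`
#' is converted to degC on read.
#'
#' @param path file written by [write_fields()] (or assembled by hand in the
#'   same layout).
#' @return an `env_fieldset`.
#' @export
read_fields <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (d in c("lat", "lon", "time_atmos", "time_ocean")) {
    if (is.null(obj$dimensions[[d]])) {
      stop("format error: missing dimension '", d, "'", call. = FALSE)
    }
  }
  dims <- lapply(obj$dimensions, as.numeric)
  out <- list(lat = dims$lat, lon = dims$lon,
              time_atmos = dims$time_atmos, time_ocean = dims$time_ocean)
  for (v in names(.ENV_VARS)) {
    entry <- obj$variables[[v]]
    if (is.null(entry)) {
      stop("format error: missing variable '", v, "'", call. = FALSE)
    }
    time_axis <- if (v %in% c("uo", "vo")) dims$time_ocean else dims$time_atmos
    arr <- array(as.numeric(entry$data),
                 dim = c(length(time_axis), length(dims$lat),
                         length(dims$lon)))
    units <- entry$units
    if (v == "sat" && identical(units, "K")) arr <- arr - 273.15
    out[[v]] <- arr
  }
  structure(out, class = "env_fieldset")
}
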