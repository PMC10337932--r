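#' @title Synthetic Pacific environmental fields
#'
#' @description
#' Generates gridded, time-varying surface air temperature (SAT), 10-m wind,
#' downward shortwave radiation and surface-current fields that carry the
#' climatological structure the voyage/energy-balance analysis relies on:
#' a latitudinal temperature gradient, hemispherically opposed seasonal
#' cycles, trade-wind and westerly belts, solar geometry with cloud
#' attenuation, zonal current bands, and an ENSO-like interannual anomaly.
#' Everything is a deterministic function of the configuration seed, so the
#' whole downstream pipeline is reproducible bit-for-bit without any
#' reanalysis download.
#'
#' @name synthetic_env
NULL

SOLAR_CONSTANT <- 1361   # W/m^2 at top of atmosphere
CLEAR_SKY_TRANSMITTANCE <- 0.75

#' Grid specification for synthetic fields
#'
#' @param lat_min,lat_max,lon_min,lon_max domain bounds in degrees; longitudes
#'   in the 0--360 convention (the default domain spans the central/south
#'   Pacific including Tahiti, Hawaii and northern New Zealand).
#' @param resolution grid spacing in degrees (> 0).
#' @param time_start,time_end hours since the calendar origin
#'   (see [day_of_year()]); `time_end > time_start`.
#' @param atmos_step atmosphere time step in hours (1 is the energy-balance
#'   target resolution; 6 is acceptable for sailing-only work).
#' @param ocean_step ocean (current) time step in hours; currents are held
#'   constant within each step when sampled.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(lat_min = -55, lat_max = 30, lon_min = 160, lon_max = 235,
                      resolution = 0.25, time_start = 0,
                      time_end = HOURS_PER_YEAR, atmos_step = 6,
                      ocean_step = 24) {
  stopifnot(resolution > 0, lat_min < lat_max,
            lat_min >= -90, lat_max <= 90,
            lon_min < lon_max, time_end > time_start,
            atmos_step > 0, 24 %% 1 == 0, ocean_step > 0)
  structure(list(lat_min = lat_min, lat_max = lat_max, lon_min = lon_min,
                 lon_max = lon_max, resolution = resolution,
                 time_start = time_start, time_end = time_end,
                 atmos_step = atmos_step, ocean_step = ocean_step),
            class = "grid_spec")
}

#' Climate configuration for the synthetic generator
#'
#' Defaults describe a plausible central-Pacific mean state: ~27 degC
#' equatorial SAT decaying poleward, a seasonal cycle growing with latitude
#' and peaking in mid-January (SH) / mid-July (NH), easterly trades near 15
#' degrees and westerlies near 45 degrees in each hemisphere, westward
#' equatorial currents with an eastward countercurrent and a mid-latitude
#' eastward drift, and a fixed zonal SAT/wind anomaly pattern for El Nino /
#' La Nina years.
#'
#' @param seed integer; fixes every generated field bit-for-bit.
#' @param equator_sat mean SAT at the equator, degC.
#' @param polar_gradient SAT decrease per degree of latitude, degC/deg.
#' @param seasonal_amplitude peak-to-mean seasonal SAT swing at/above 40
#'   degrees latitude, degC (scales down linearly toward the equator).
#' @param enso_phase one of `"nino"`, `"neutral"`, `"nina"`.
#' @param enso_sat_anomaly peak SAT anomaly magnitude of the ENSO pattern, degC.
#' @param wind_belt_params list with `trade_speed`, `trade_center`,
#'   `trade_width`, `westerly_speed`, `westerly_center`, `westerly_width`
#'   (speeds m/s, latitudes degrees).
#' @param cloud_attenuation base cloud attenuation of surface shortwave,
#'   in `[0, 1]`.
#' @param current_band_params list of zonal bands, each
#'   `list(speed, center, width)` with eastward-positive speed in m/s.
#' @param noise_scales named numeric vector of weather-noise standard
#'   deviations for `sat` (degC), `wind` (m/s), `current` (m/s).
#' @return an object of class `climate_config`.
#' @export
climate_config <- function(seed = 1L,
                           equator_sat = 27,
                           polar_gradient = 0.45,
                           seasonal_amplitude = 6,
                           enso_phase = c("neutral", "nino", "nina"),
                           enso_sat_anomaly = 1.5,
                           wind_belt_params = list(
                             trade_speed = 7, trade_center = 14,
                             trade_width = 13, westerly_speed = 9,
                             westerly_center = 43, westerly_width = 14),
                           cloud_attenuation = 0.35,
                           current_band_params = list(
                             sec  = list(speed = -0.25, center = -8, width = 8),
                             nec  = list(speed = -0.20, center = 12, width = 5),
                             necc = list(speed = 0.15, center = 6, width = 3),
                             stcc = list(speed = 0.12, center = -42, width = 8)),
                           noise_scales = c(sat = 1.0, wind = 3.0,
                                            current = 0.05)) {
  enso_phase <- match.arg(enso_phase)
  stopifnot(cloud_attenuation >= 0, cloud_attenuation <= 1,
            seasonal_amplitude >= 0, enso_sat_anomaly >= 0,
            all(noise_scales >= 0))
  structure(list(seed = as.integer(seed), equator_sat = equator_sat,
                 polar_gradient = polar_gradient,
                 seasonal_amplitude = seasonal_amplitude,
                 enso_phase = enso_phase, enso_sat_anomaly = enso_sat_anomaly,
                 wind_belt_params = wind_belt_params,
                 cloud_attenuation = cloud_attenuation,
                 current_band_params = current_band_params,
                 noise_scales = noise_scales),
            class = "climate_config")
}

# ENSO phase as a signed factor: +1 El Nino, 0 neutral, -1 La Nina
.enso_sign <- function(phase) switch(phase, nino = 1, neutral = 0, nina = -1)

# Gaussian belt helper, mirrored across the equator when mirror = TRUE
.belt <- function(lat, center, width, mirror = TRUE) {
  if (mirror) {
    exp(-((abs(lat) - abs(center)) / width)^2)
  } else {
    exp(-((lat - center) / width)^2)
  }
}

# Climatological-mean SAT (degC) by latitude
.sat_mean <- function(cfg, lat) cfg$equator_sat - cfg$polar_gradient * abs(lat)

# Seasonal SAT anomaly: amplitude grows linearly with |lat| up to 40 deg,
# peak mid-January (doy 15) south of the equator, mid-July (doy 196) north.
.sat_seasonal <- function(cfg, lat, doy) {
  amp <- cfg$seasonal_amplitude * pmin(abs(lat) / 40, 1)
  phase_doy <- ifelse(lat < 0, 15, 196)
  amp * cos(2 * pi * (doy - phase_doy) / 365)
}

# Fixed zonal ENSO anomaly pattern (degC), strongest in the eastern
# equatorial part of the domain.
.sat_enso <- function(cfg, lat, lon, lon_min, lon_max) {
  f <- .enso_sign(cfg$enso_phase)
  if (f == 0) return(lat * 0 + lon * 0)
  ramp <- pmin(pmax((lon - lon_min) / max(lon_max - lon_min, 1), 0), 1)
  f * cfg$enso_sat_anomaly * exp(-(lat / 12)^2) * ramp
}

# Mean zonal wind (m/s, eastward positive): one easterly trade belt and one
# westerly belt per hemisphere, as overlapping Gaussians whose shoulders
# meet near the equator (narrow doldrums) and near 30 degrees (horse
# latitudes).
.wind_u_mean <- function(cfg, lat) {
  wb <- cfg$wind_belt_params
  -wb$trade_speed * (.belt(lat, -wb$trade_center, wb$trade_width, FALSE) +
                       .belt(lat, wb$trade_center, wb$trade_width, FALSE)) +
    wb$westerly_speed * .belt(lat, wb$westerly_center, wb$westerly_width)
}

# Mean meridional wind: trades converge on the equator.
.wind_v_mean <- function(cfg, lat) {
  wb <- cfg$wind_belt_params
  1.5 * (.belt(lat, -wb$trade_center, wb$trade_width, FALSE) +
           .belt(lat, wb$trade_center, wb$trade_width, FALSE)) * sign(-lat)
}

# ENSO wind anomaly: westerly anomaly (weakened trades) near the equator
# during El Nino, the reverse for La Nina.
.wind_u_enso <- function(cfg, lat) {
  1.5 * .enso_sign(cfg$enso_phase) * exp(-(lat / 10)^2)
}

# Zonal surface current (m/s) from the configured band list.
.current_u_mean <- function(cfg, lat) {
  u <- lat * 0
  for (band in cfg$current_band_params) {
    u <- u + band$speed * .belt(lat, band$center, band$width, mirror = FALSE)
  }
  u
}

# Effective cloud attenuation: base value, enhanced in the ITCZ band and in
# the winter-hemisphere storm belts; capped at 0.9.
.cloud_eff <- function(cfg, lat, doy) {
  winterness <- ifelse(lat < 0,
                       0.5 * (1 + cos(2 * pi * (doy - 196) / 365)),
                       0.5 * (1 + cos(2 * pi * (doy - 15) / 365)))
  ca <- cfg$cloud_attenuation * (1 + 0.3 * exp(-(lat / 6)^2)) +
    0.10 * .belt(lat, 45, 12) * winterness
  pmin(ca, 0.9)
}

#' Clear-sky solar elevation factor
#'
#' Cosine of the solar zenith angle (clamped at zero below the horizon) from
#' day-of-year declination and the local hour angle.
#'
#' @param lat latitude, degrees.
#' @param lon longitude, degrees (used for local solar time).
#' @param doy day of year.
#' @param hour_utc fractional UTC hour of day.
#' @return cos(zenith), zero at night. Vectorised.
#' @export
solar_cos_zenith <- function(lat, lon, doy, hour_utc) {
  decl <- deg2rad(-23.44 * cos(2 * pi * (doy + 10) / 365))
  lst <- hour_utc + wrap_lon(lon) / 15          # local solar time, hours
  ha <- deg2rad(15 * (lst - 12))                # hour angle
  phi <- deg2rad(lat)
  pmax(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha), 0)
}

# Smooth, seeded "weather" noise: a sum of travelling sinusoids in
# (time, lat, lon). Returns an array with dim (nt, nlat, nlon). sd scales
# the pointwise standard deviation (each mode carries sd/sqrt(n_modes/2)).
.travelling_noise <- function(sd, t_hours, lat, lon, n_modes = 6) {
  out <- array(0, dim = c(length(t_hours), length(lat), length(lon)))
  if (sd == 0) return(out)
  amp <- sd * sqrt(2 / n_modes)
  for (j in seq_len(n_modes)) {
    period_h <- stats::runif(1, 2, 10) * 24          # 2-10 day weather
    wavelen_lon <- stats::runif(1, 20, 60)           # degrees
    wavelen_lat <- stats::runif(1, 15, 40)
    phi <- stats::runif(1, 0, 2 * pi)
    tp <- 2 * pi * t_hours / period_h
    lap <- 2 * pi * lat / wavelen_lat
    lop <- 2 * pi * lon / wavelen_lon
    out <- out + amp * sin(outer(outer(tp, lap, "+"), lop, "+") + phi)
  }
  out
}

# replicate a (lat) profile / (t,lat) matrix into the (t, lat, lon) cube
.bcast_lat <- function(prof, nt, nlon) {
  aperm(array(prof, dim = c(length(prof), nt, nlon)), c(2, 1, 3))
}
.bcast_tlat <- function(m, nlon) array(m, dim = c(dim(m), nlon))

#' Generate a complete synthetic environmental field set
#'
#' @param config a [climate_config()].
#' @param grid a [grid_spec()].
#' @return an object of class `env_fieldset`: coordinate vectors `lat`,
#'   `lon`, `time_atmos`, `time_ocean` plus arrays `sat` (degC), `u10`, `v10`
#'   (m/s), `ssrd` (W/m^2, always >= 0, zero at local night) and `uo`, `vo`
#'   (m/s), each with dim (time, lat, lon).
#' @details The wind-belt configuration must intersect the grid: a domain
#'   that contains neither hemisphere's trade belt raises a configuration
#'   error, since the voyage model is meaningless without it.
#' @export
generate_fields <- function(config, grid) {
  stopifnot(inherits(config, "climate_config"), inherits(grid, "grid_spec"))
  wb <- config$wind_belt_params
  belt_lo <- abs(wb$trade_center) - wb$trade_width / 2
  belt_hi <- abs(wb$trade_center) + wb$trade_width / 2
  if (!(grid$lat_max >= belt_lo && grid$lat_min <= belt_hi) &&
      !(grid$lat_min <= -belt_lo && grid$lat_max >= -belt_hi)) {
    stop("configuration error: grid domain [", grid$lat_min, ", ",
         grid$lat_max, "] contains no trade-wind belt", call. = FALSE)
  }

  lat <- seq(grid$lat_min, grid$lat_max, by = grid$resolution)
  lon <- seq(grid$lon_min, grid$lon_max, by = grid$resolution)
  t_atm <- seq(grid$time_start, grid$time_end, by = grid$atmos_step)
  t_ocn <- seq(grid$time_start, grid$time_end, by = grid$ocean_step)
  nt <- length(t_atm); nlat <- length(lat); nlon <- length(lon)

  doy <- day_of_year(t_atm)
  hod <- hour_of_day(t_atm)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  ns <- config$noise_scales
  ns_sat <- if ("sat" %in% names(ns)) ns[["sat"]] else 0
  ns_wind <- if ("wind" %in% names(ns)) ns[["wind"]] else 0
  ns_cur <- if ("current" %in% names(ns)) ns[["current"]] else 0

  # --- SAT: mean(lat) + seasonal(lat, doy) + ENSO(lat, lon) + noise
  seas <- outer(doy, lat, function(d, la) .sat_seasonal(config, la, d))
  sat <- .bcast_lat(.sat_mean(config, lat), nt, nlon) +
    .bcast_tlat(seas, nlon) +
    aperm(array(outer(lat, lon, function(la, lo)
      .sat_enso(config, la, lo, grid$lon_min, grid$lon_max)),
      dim = c(nlat, nlon, nt)), c(3, 1, 2)) +
    .travelling_noise(ns_sat, t_atm, lat, lon)

  # --- wind
  u10 <- .bcast_lat(.wind_u_mean(config, lat) + .wind_u_enso(config, lat),
                    nt, nlon) +
    .travelling_noise(ns_wind, t_atm, lat, lon)
  v10 <- .bcast_lat(.wind_v_mean(config, lat), nt, nlon) +
    .travelling_noise(0.5 * ns_wind, t_atm, lat, lon)

  # --- downward shortwave: TOA geometry x clear-sky transmittance x clouds
  cosz <- array(0, dim = c(nt, nlat, nlon))
  for (k in seq_len(nlon)) {
    cosz[, , k] <- outer(seq_len(nt), lat, function(i, la)
      solar_cos_zenith(la, lon[k], doy[i], hod[i]))
  }
  cloud <- .bcast_tlat(outer(doy, lat, function(d, la)
    .cloud_eff(config, la, d)), nlon)
  ssrd <- SOLAR_CONSTANT * CLEAR_SKY_TRANSMITTANCE * cosz * (1 - cloud)

  # --- currents (daily): zonal bands + weak noise, constant within a day
  nto <- length(t_ocn)
  uo <- .bcast_lat(.current_u_mean(config, lat), nto, nlon) +
    .travelling_noise(ns_cur, t_ocn, lat, lon)
  vo <- .travelling_noise(ns_cur, t_ocn, lat, lon)

  structure(list(lat = lat, lon = lon, time_atmos = t_atm, time_ocean = t_ocn,
                 sat = sat, u10 = u10, v10 = v10, ssrd = ssrd,
                 uo = uo, vo = vo,
                 config = config, grid = grid),
            class = "env_fieldset")
}

#' @export
print.env_fieldset <- function(x, ...) {
  cat("<env_fieldset> ", length(x$lat), "lat x", length(x$lon), "lon,",
      length(x$time_atmos), "atmos steps,", length(x$time_ocean),
      "ocean steps\n")
  cat("  lat:", min(x$lat), "..", max(x$lat),
      " lon:", min(x$lon), "..", max(x$lon),
      " t:", min(x$time_atmos), "..", max(x$time_atmos), "h\n")
  invisible(x)
}

# index/weight pair for linear interpolation along a sorted coordinate
.interp_ix <- function(coord, x) {
  i <- findInterval(x, coord, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(coord) - 1)
  w <- (x - coord[i]) / (coord[i + 1] - coord[i])
  list(i = i, w = pmin(pmax(w, 0), 1))
}

# trilinear (time-linear, space-bilinear) evaluation of one (t,lat,lon) array
.interp_cube <- function(arr, ti, la, lo) {
  g <- function(it, ia, io) arr[cbind(it, ia, io)]
  v00 <- g(ti$i, la$i, lo$i) * (1 - ti$w) + g(ti$i + 1, la$i, lo$i) * ti$w
  v10 <- g(ti$i, la$i + 1, lo$i) * (1 - ti$w) + g(ti$i + 1, la$i + 1, lo$i) * ti$w
  v01 <- g(ti$i, la$i, lo$i + 1) * (1 - ti$w) + g(ti$i + 1, la$i, lo$i + 1) * ti$w
  v11 <- g(ti$i, la$i + 1, lo$i + 1) * (1 - ti$w) +
    g(ti$i + 1, la$i + 1, lo$i + 1) * ti$w
  (v00 * (1 - la$w) + v10 * la$w) * (1 - lo$w) +
    (v01 * (1 - la$w) + v11 * la$w) * lo$w
}

#' Sample environmental fields at points
#'
#' Bilinear interpolation in space and linear interpolation in time for the
#' atmospheric fields; currents are held constant within each ocean time step
#' (piecewise-constant in time). Values at grid nodes and stored time steps
#' are returned exactly. Vectorised over `lat`, `lon`, `t`.
#'
#' @param fieldset an `env_fieldset`.
#' @param lat,lon query positions, degrees (longitude any convention).
#' @param t query times, hours since the calendar origin.
#' @return a data.frame with columns `ta` (degC), `wind_u`, `wind_v`, `ws10`
#'   (m/s), `solar` (W/m^2), `cur_u`, `cur_v` (m/s).
#' @export
sample_env <- function(fieldset, lat, lon, t) {
  lon <- wrap_lon(lon)
  n <- max(length(lat), length(lon), length(t))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n); t <- rep_len(t, n)
  if (any(!in_domain(fieldset, lat, lon, t))) {
    stop("out-of-domain: query point outside the field domain", call. = FALSE)
  }
  la <- .interp_ix(fieldset$lat, lat)
  lo <- .interp_ix(fieldset$lon, lon)
  ti <- .interp_ix(fieldset$time_atmos, t)
  to <- .interp_ix(fieldset$time_ocean, t)
  to$w <- to$w * 0                      # currents constant within each day

  ta <- .interp_cube(fieldset$sat, ti, la, lo)
  u10 <- .interp_cube(fieldset$u10, ti, la, lo)
  v10 <- .interp_cube(fieldset$v10, ti, la, lo)
  solar <- pmax(.interp_cube(fieldset$ssrd, ti, la, lo), 0)
  cur_u <- .interp_cube(fieldset$uo, to, la, lo)
  cur_v <- .interp_cube(fieldset$vo, to, la, lo)
  data.frame(ta = ta, wind_u = u10, wind_v = v10,
             ws10 = sqrt(u10^2 + v10^2), solar = solar,
             cur_u = cur_u, cur_v = cur_v)
}

#' Test whether points lie inside a fieldset's space-time domain
#'
#' @inheritParams sample_env
#' @return logical vector.
#' @export
in_domain <- function(fieldset, lat, lon, t) {
  lon <- wrap_lon(lon)
  lat >= min(fieldset$lat) & lat <= max(fieldset$lat) &
    lon >= min(fieldset$lon) & lon <= max(fieldset$lon) &
    t >= min(fieldset$time_atmos) & t <= max(fieldset$time_atmos)
}
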