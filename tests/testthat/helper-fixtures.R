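# Shared fixtures: tiny field sets built in code, plus independent
# brute-force oracles kept deliberately separate from the package internals.

# small default-climate fieldset (coarse grid, short window) for sampling
# and voyage tests
tiny_fieldset <- function(seed = 11, days = 30, resolution = 5,
                          atmos_step = 6) {
  generate_fields(
    climate_config(seed = seed),
    grid_spec(resolution = resolution, time_end = days * 24,
              atmos_step = atmos_step))
}

# hand-built fieldset with spatially/temporally constant values; bypasses
# the generator so voyage tests control the world exactly
const_fieldset <- function(ta = 25, wind_u = 0, wind_v = 0, solar = 0,
                           cur_u = 0, cur_v = 0,
                           lat = seq(-55, 30, by = 5),
                           lon = seq(160, 235, by = 5),
                           t_atm = seq(0, 60 * 24, by = 6),
                           t_ocn = seq(0, 60 * 24, by = 24)) {
  cube <- function(v, tt) array(v, dim = c(length(tt), length(lat), length(lon)))
  structure(list(lat = lat, lon = lon, time_atmos = t_atm, time_ocean = t_ocn,
                 sat = cube(ta, t_atm), u10 = cube(wind_u, t_atm),
                 v10 = cube(wind_v, t_atm), ssrd = cube(solar, t_atm),
                 uo = cube(cur_u, t_ocn), vo = cube(cur_v, t_ocn)),
            class = "env_fieldset")
}

# independent brute-force bilinear+linear-time interpolation of one field
brute_interp <- function(coords_t, coords_lat, coords_lon, arr, t, lat, lon) {
  bracket <- function(coord, x) {
    i <- max(which(coord <= x + 1e-12))
    i <- min(i, length(coord) - 1)
    w <- (x - coord[i]) / (coord[i + 1] - coord[i])
    c(i = i, w = max(0, min(1, w)))
  }
  bt <- bracket(coords_t, t); ba <- bracket(coords_lat, lat)
  bo <- bracket(coords_lon, lon)
  acc <- 0
  for (dt in 0:1) for (da in 0:1) for (dl in 0:1) {
    wt <- if (dt == 0) 1 - bt["w"] else bt["w"]
    wa <- if (da == 0) 1 - ba["w"] else ba["w"]
    wl <- if (dl == 0) 1 - bo["w"] else bo["w"]
    acc <- acc + wt * wa * wl *
      arr[bt["i"] + dt, ba["i"] + da, bo["i"] + dl]
  }
  unname(acc)
}

# a fabricated trip object with prescribed 6-hourly positions, for
# departure_env tests (not produced by the simulator on purpose)
fake_trip <- function(lats, lons, departure_hours = 0,
                      destination = "hawaii", vessel = 1) {
  t <- departure_hours + (seq_along(lats) - 1) * 6
  structure(list(points = data.frame(t = t, lat = lats, lon = lons),
                 departure_hours = departure_hours,
                 departure_day = unname(day_of_year(departure_hours)),
                 year = unname(year_index(departure_hours)),
                 destination = destination, vessel = vessel,
                 outcome = "arrived",
                 duration_days = (max(t) - departure_hours) / 24),
            class = "eb_trip")
}

std_body <- function() body_type("female", 170, 70, 0.005, "B1")
std_exposure <- function() default_exposures()$Hhl
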