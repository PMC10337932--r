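#' @title Voyage simulation
#'
#' @description
#' Advances sailing canoes from Tahiti toward Hawaii or the NE coast of
#' Te Ika-a-Maui (North Island, New Zealand). At every 6-hour step the
#' vessel displacement is the sum of the surface-current drift and a
#' sailing-induced velocity; the sailing speed comes from a polar table
#' (boat-speed / wind-speed ratio as a function of true-wind angle off the
#' heading) and the heading is chosen to maximise velocity made good toward
#' the great-circle bearing to the target. Sixteen vessels depart every
#' five days (eight per destination), for 73 departure slots per 365-day
#' year; a trip ends on arrival, after 50 days, or when it exits the field
#' domain.
#'
#' The replica-canoe polar the analysis is calibrated against is not
#' published as numbers; the default here is a documented parametric
#' stand-in with magnitudes consistent with replica-canoe performance
#' (zero inside a 45-degree no-go zone, 0.35 at 90, 0.45 at 135, 0.40 at
#' 180 degrees, 5 m/s cap) and is fully overridable.
#'
#' @name voyage_sim
NULL

#' Standard route endpoints (degrees; lon in 0--360)
#'
#' Departure is Tahiti; targets are a point on the southern coast of
#' Hawai'i island and a point off the NE coast of Te Ika-a-Maui.
#' @return named list of `c(lat, lon)` vectors.
#' @export
route_points <- function() {
  list(tahiti = c(lat = -17.53, lon = 210.42),
       hawaii = c(lat = 19.0, lon = 204.4),
       new_zealand = c(lat = -37.7, lon = 178.5))
}

#' Vessel sailing polar
#'
#' @param angles true-wind angles off the heading, degrees in `[0, 180]`,
#'   increasing, covering 0 and 180.
#' @param ratios boat-speed / wind-speed ratios at `angles` (>= 0; must be 0
#'   for angles inside the no-go zone).
#' @param max_speed hard cap on sailing speed, m/s.
#' @param no_go_angle angles closer to upwind than this sail at zero speed.
#' @return an object of class `vessel_polar`.
#' @export
vessel_polar <- function(angles = c(0, 45, 90, 135, 180),
                         ratios = c(0, 0, 0.35, 0.45, 0.40),
                         max_speed = 5, no_go_angle = 45) {
  stopifnot(length(angles) == length(ratios), !is.unsorted(angles),
            angles[1] == 0, angles[length(angles)] == 180,
            all(ratios >= 0), max_speed > 0, no_go_angle >= 0)
  if (any(ratios[angles < no_go_angle] != 0)) {
    stop("polar ratios must be zero inside the no-go zone", call. = FALSE)
  }
  structure(list(angles = angles, ratios = ratios, max_speed = max_speed,
                 no_go_angle = no_go_angle), class = "vessel_polar")
}

#' Evaluate a polar's speed ratio
#'
#' Linear interpolation of the ratio table at the folded true-wind angle;
#' exactly zero inside the no-go zone.
#'
#' @param polar a [vessel_polar()].
#' @param twa true-wind angle(s) off the heading, degrees (any sign; folded
#'   to `[0, 180]`).
#' @return ratio(s) >= 0.
#' @export
polar_ratio <- function(polar, twa) {
  twa <- fold_angle(twa)
  r <- stats::approx(polar$angles, polar$ratios, xout = twa, rule = 2)$y
  ifelse(twa < polar$no_go_angle, 0, r)
}

#' Sailing velocity for a heading in a given wind
#'
#' The boat sails along `heading` at `WS * ratio(twa)` capped at the polar's
#' maximum speed, where `twa` is the angle between the heading and the
#' direction the wind comes from. Zero wind gives zero sailing velocity.
#'
#' @param polar a [vessel_polar()].
#' @param wind_u,wind_v wind components, m/s (direction wind blows toward).
#' @param heading compass heading(s), degrees in `[0, 360)`.
#' @return data.frame with sailing components `u`, `v` (m/s).
#' @export
sailing_velocity <- function(polar, wind_u, wind_v, heading) {
  ws <- sqrt(wind_u^2 + wind_v^2)
  n <- max(length(ws), length(heading))
  ws <- rep_len(ws, n); heading <- rep_len(heading, n)
  wind_from <- (uv_to_heading(rep_len(wind_u, n), rep_len(wind_v, n)) + 180) %% 360
  twa <- fold_angle(wind_from - heading)
  speed <- pmin(ws * polar_ratio(polar, twa), polar$max_speed)
  speed[ws == 0] <- 0
  uv <- heading_to_uv(heading, speed)
  data.frame(u = uv$u, v = uv$v)
}

#' Choose the heading maximising velocity made good
#'
#' Searches a fan of candidate headings about the great-circle bearing to
#' the target (default +/- 60 degrees in 5-degree increments) and returns
#' the one whose total velocity (sailing plus current) has the largest
#' component along the bearing. Ties (within 1e-9 m/s) are broken toward
#' the direct bearing first, then toward the smaller compass angle.
#'
#' @param lat,lon current position, degrees.
#' @param target `c(lat, lon)` of the destination.
#' @param polar a [vessel_polar()].
#' @param wind_u,wind_v wind components, m/s.
#' @param cur_u,cur_v current components, m/s (default 0: pure-sailing VMG).
#' @param fan_half_width,fan_step fan geometry, degrees.
#' @return list with `heading` (degrees), `vmg` (m/s).
#' @export
choose_heading <- function(lat, lon, target, polar, wind_u, wind_v,
                           cur_u = 0, cur_v = 0,
                           fan_half_width = 60, fan_step = 5) {
  bearing <- gc_bearing(lat, lon, target[["lat"]], target[["lon"]])
  offsets <- seq(-fan_half_width, fan_half_width, by = fan_step)
  cand <- (bearing + offsets) %% 360
  sail <- sailing_velocity(polar, wind_u, wind_v, cand)
  bu <- sin(deg2rad(bearing)); bv <- cos(deg2rad(bearing))
  vmg <- (sail$u + cur_u) * bu + (sail$v + cur_v) * bv
  best <- max(vmg)
  tied <- which(vmg >= best - 1e-9)
  tied <- tied[order(abs(offsets[tied]), cand[tied])]
  list(heading = cand[tied[1]], vmg = vmg[tied[1]])
}

#' Simulation configuration
#'
#' @param step integration step, hours (must divide 24).
#' @param max_duration trip cap, days.
#' @param arrival_radius arrival detection radius, km.
#' @param departure_interval days between departure slots.
#' @param vessels_per_departure vessels per departure day per destination.
#' @param heading_noise_sd per-step compass noise differentiating the
#'   vessels of one departure, degrees (0 makes all eight identical).
#' @param fan_half_width,fan_step heading-search fan, degrees.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(step = 6, max_duration = 50, arrival_radius = 50,
                       departure_interval = 5, vessels_per_departure = 8,
                       heading_noise_sd = 5, fan_half_width = 60,
                       fan_step = 5) {
  stopifnot(step > 0, 24 %% step == 0, max_duration > 0, arrival_radius > 0,
            departure_interval > 0, vessels_per_departure > 0,
            heading_noise_sd >= 0)
  structure(list(step = step, max_duration = max_duration,
                 arrival_radius = arrival_radius,
                 departure_interval = departure_interval,
                 vessels_per_departure = vessels_per_departure,
                 heading_noise_sd = heading_noise_sd,
                 fan_half_width = fan_half_width, fan_step = fan_step),
            class = "sim_config")
}

#' Departure schedule
#'
#' Vessels leave every `departure_interval` days starting on day 1 of each
#' simulated year; with the default 5-day interval that is 73 slots per
#' 365-day year, 8 vessels per destination per slot, hence
#' 8 x 73 x 3 = 1752 trips per destination over a three-year design.
#'
#' @param config a [sim_config()].
#' @param n_years number of simulated years (>= 0).
#' @param destinations destination names.
#' @return data.frame with columns `year`, `departure_day` (day of year),
#'   `departure_hours` (hours since origin), `destination`, `vessel`.
#' @export
schedule_departures <- function(config, n_years,
                                destinations = c("hawaii", "new_zealand")) {
  stopifnot(inherits(config, "sim_config"), n_years >= 0)
  if (n_years == 0) {
    return(data.frame(year = integer(), departure_day = integer(),
                      departure_hours = numeric(), destination = character(),
                      vessel = integer()))
  }
  days <- seq(1, 365, by = config$departure_interval)
  grid <- expand.grid(vessel = seq_len(config$vessels_per_departure),
                      destination = destinations, departure_day = days,
                      year = seq_len(n_years), stringsAsFactors = FALSE)
  grid$departure_hours <- (grid$year - 1) * HOURS_PER_YEAR +
    (grid$departure_day - 1) * 24
  grid[, c("year", "departure_day", "departure_hours", "destination",
           "vessel")]
}

#' Simulate one trip
#'
#' @param departure_hours departure time, hours since the calendar origin.
#' @param destination `"hawaii"` or `"new_zealand"` (or any name present in
#'   `targets`).
#' @param fieldset an `env_fieldset`.
#' @param polar a [vessel_polar()].
#' @param config a [sim_config()].
#' @param vessel vessel index within the departure (seeds the heading
#'   noise); vessels of one departure differ only through this noise.
#' @param seed base integer seed mixed with departure/vessel for the
#'   heading-noise stream.
#' @param start `c(lat, lon)` departure point (default Tahiti).
#' @param targets named list of target points (default [route_points()]).
#' @return an object of class `eb_trip`: a list with `points` (data.frame:
#'   `t`, `lat`, `lon`, `ta`, `ws10`, `solar`, `wind_u`, `wind_v`, `cur_u`,
#'   `cur_v`, `sail_u`, `sail_v`), `departure_hours`, `departure_day`,
#'   `year`, `destination`, `vessel`, `outcome` (`arrived` / `timed_out` /
#'   `exited_domain`) and `duration_days`.
#' @export
simulate_trip <- function(departure_hours, destination, fieldset, polar,
                          config = sim_config(), vessel = 1L, seed = 1L,
                          start = route_points()$tahiti,
                          targets = route_points()) {
  stopifnot(inherits(config, "sim_config"))
  target <- targets[[destination]]
  if (is.null(target)) stop("unknown destination: ", destination, call. = FALSE)
  if (!in_domain(fieldset, start[["lat"]], start[["lon"]], departure_hours)) {
    stop("configuration error: departure outside the field domain",
         call. = FALSE)
  }

  n_steps <- as.integer(config$max_duration * 24 / config$step)
  # private, reproducible heading-noise stream for this (seed, trip, vessel)
  noise <- if (config$heading_noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed((as.integer(seed) * 7919L + as.integer(departure_hours / 6) * 131L +
                match(destination, names(targets)) * 17L +
                as.integer(vessel)) %% .Machine$integer.max)
    z <- stats::rnorm(n_steps, 0, config$heading_noise_sd)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    z
  } else {
    numeric(n_steps)
  }

  pts <- vector("list", n_steps + 1)
  lat <- start[["lat"]]; lon <- wrap_lon(start[["lon"]])
  outcome <- "timed_out"
  t_end <- departure_hours
  for (i in seq_len(n_steps + 1)) {
    t <- departure_hours + (i - 1) * config$step
    if (!in_domain(fieldset, lat, lon, t)) {
      outcome <- "exited_domain"
      break
    }
    env <- sample_env(fieldset, lat, lon, t)
    ch <- choose_heading(lat, lon, target, polar, env$wind_u, env$wind_v,
                         env$cur_u, env$cur_v,
                         fan_half_width = config$fan_half_width,
                         fan_step = config$fan_step)
    hdg <- (ch$heading + noise[min(i, n_steps)]) %% 360
    sail <- sailing_velocity(polar, env$wind_u, env$wind_v, hdg)
    pts[[i]] <- data.frame(t = t, lat = lat, lon = lon, ta = env$ta,
                           ws10 = env$ws10, solar = env$solar,
                           wind_u = env$wind_u, wind_v = env$wind_v,
                           cur_u = env$cur_u, cur_v = env$cur_v,
                           sail_u = sail$u, sail_v = sail$v)
    t_end <- t
    dist <- gc_distance(lat, lon, target[["lat"]], target[["lon"]])
    if (dist <= config$arrival_radius * 1000) {
      outcome <- "arrived"
      break
    }
    if (i == n_steps + 1) break  # 50-day cap reached with the final sample
    pos <- step_position(lat, lon, sail$u + env$cur_u, sail$v + env$cur_v,
                         config$step)
    lat <- pos$lat; lon <- pos$lon
  }
  points <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  structure(list(points = points, departure_hours = departure_hours,
                 departure_day = unname(day_of_year(departure_hours)),
                 year = unname(year_index(departure_hours)),
                 destination = destination, vessel = vessel,
                 outcome = outcome,
                 duration_days = (t_end - departure_hours) / 24),
            class = "eb_trip")
}

#' @export
print.eb_trip <- function(x, ...) {
  cat(sprintf("<eb_trip> %s vessel %d, depart day %d yr %d: %s after %.2f days (%d pts)\n",
              x$destination, x$vessel, x$departure_day, x$year, x$outcome,
              x$duration_days, nrow(x$points)))
  invisible(x)
}

#' Simulate every scheduled trip
#'
#' @param schedule data.frame from [schedule_departures()], optionally
#'   subset.
#' @param fieldset,polar,config,seed,start,targets as in [simulate_trip()].
#' @param progress print a line per departure day.
#' @return list of `eb_trip` objects, in schedule order.
#' @export
simulate_all <- function(schedule, fieldset, polar = vessel_polar(),
                         config = sim_config(), seed = 1L,
                         start = route_points()$tahiti,
                         targets = route_points(), progress = FALSE) {
  lapply(seq_len(nrow(schedule)), function(i) {
    row <- schedule[i, ]
    if (progress && row$vessel == 1 && row$destination == "hawaii") {
      message("departure day ", row$departure_day, " year ", row$year)
    }
    simulate_trip(row$departure_hours, row$destination, fieldset, polar,
                  config, vessel = row$vessel, seed = seed, start = start,
                  targets = targets)
  })
}

#' Write a trip to CSV
#'
#' One CSV per trip: `# key: value` header lines carrying the trip metadata
#' (destination, outcome, duration) followed by the point table.
#'
#' @param trip an `eb_trip`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trip_csv <- function(trip, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(destination = trip$destination, vessel = trip$vessel,
            departure_day = trip$departure_day, year = trip$year,
            outcome = trip$outcome,
            duration_days = format(trip$duration_days, digits = 10))
  writeLines(paste0("# ", names(meta), ": ", meta), con)
  utils::write.csv(trip$points, con, row.names = FALSE)
  invisible(path)
}
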