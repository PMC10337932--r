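# Voyage simulation

test_that("sailing velocity follows the polar rule", {
  polar <- vessel_polar()
  # no wind -> no sailing speed, any heading
  z <- sailing_velocity(polar, 0, 0, 123)
  expect_equal(c(z$u, z$v), c(0, 0))
  # wind dead ahead inside the no-go zone -> zero
  # (heading north, wind blowing toward the south comes from dead ahead)
  z <- sailing_velocity(polar, 0, -10, 0)
  expect_equal(c(z$u, z$v), c(0, 0))
  # 10 m/s beam wind, ratio 0.4 at 90 deg, heading due north -> (0, 4)
  polar2 <- vessel_polar(angles = c(0, 45, 90, 135, 180),
                         ratios = c(0, 0, 0.4, 0.45, 0.40))
  z <- sailing_velocity(polar2, -10, 0, 0)   # wind from the east, beam
  expect_equal(z$u, 0, tolerance = 1e-12)
  expect_equal(z$v, 4, tolerance = 1e-12)
  # cap applies
  polar3 <- vessel_polar(max_speed = 2)
  z <- sailing_velocity(polar3, -20, 0, 0)
  expect_equal(sqrt(z$u^2 + z$v^2), 2)
})

test_that("polar validation rejects nonzero ratios in the no-go zone", {
  expect_error(vessel_polar(angles = c(0, 30, 90, 180),
                            ratios = c(0, 0.2, 0.4, 0.4), no_go_angle = 45),
               "no-go")
})

test_that("heading choice: downwind optimum equals the bearing", {
  # a polar whose ratio peaks dead downwind, so the run is the optimum
  polar <- vessel_polar(ratios = c(0, 0, 0.30, 0.38, 0.45))
  # target due north of the start; wind from directly astern (southerly)
  ch <- choose_heading(0, 200, c(lat = 10, lon = 200), polar, 0, 8)
  expect_equal(ch$heading, 0)
  expect_gt(ch$vmg, 0)
})

test_that("heading choice: dead-ahead wind picks the smaller compass tack", {
  polar <- vessel_polar()
  ch <- choose_heading(0, 200, c(lat = 10, lon = 200), polar, 0, -8)
  # symmetric tacks exist at +/- offset; tie-break selects the smaller
  # compass angle (the eastern tack)
  expect_lte(ch$heading, 180)
  expect_gt(ch$heading, 0)
  east <- ch$heading
  # and the mirrored VMG at 360 - heading is identical
  s1 <- sailing_velocity(polar, 0, -8, east)
  s2 <- sailing_velocity(polar, 0, -8, 360 - east)
  expect_equal(s1$v, s2$v, tolerance = 1e-12)
})

test_that("fan search matches a 1-degree brute force within one step", {
  polar <- vessel_polar()
  set.seed(17)
  for (k in 1:20) {
    lat <- runif(1, -40, 20); lon <- runif(1, 170, 230)
    tgt <- c(lat = runif(1, -40, 20), lon = runif(1, 170, 230))
    if (abs(tgt[["lat"]] - lat) < 1 && abs(tgt[["lon"]] - lon) < 1) next
    wu <- runif(1, -12, 12); wv <- runif(1, -12, 12)
    cu <- runif(1, -0.3, 0.3); cv <- runif(1, -0.3, 0.3)
    ch <- choose_heading(lat, lon, tgt, polar, wu, wv, cu, cv)
    # brute force over every integer heading in the same fan
    bearing <- gc_bearing(lat, lon, tgt[["lat"]], tgt[["lon"]])
    cand <- (bearing + seq(-60, 60, by = 1)) %% 360
    sail <- sailing_velocity(polar, wu, wv, cand)
    vmg <- (sail$u + cu) * sin(bearing * pi / 180) +
      (sail$v + cv) * cos(bearing * pi / 180)
    # optimum from the 5-degree fan within one interpolation step of the
    # 1-degree optimum
    best1 <- max(vmg)
    ws <- sqrt(wu^2 + wv^2)
    expect_gte(ch$vmg, best1 - ws * 0.35 * (5 * pi / 180) - 1e-9)
  }
})

test_that("positive-VMG headings are never passed over for negative ones", {
  polar <- vessel_polar()
  set.seed(19)
  for (k in 1:20) {
    wu <- runif(1, -10, 10); wv <- runif(1, -10, 10)
    ch <- choose_heading(-10, 200, c(lat = 0, lon = 210), polar, wu, wv)
    cand <- (gc_bearing(-10, 200, 0, 210) + seq(-60, 60, by = 5)) %% 360
    sail <- sailing_velocity(polar, wu, wv, cand)
    b <- gc_bearing(-10, 200, 0, 210) * pi / 180
    any_pos <- any(sail$u * sin(b) + sail$v * cos(b) > 0)
    if (any_pos) expect_gte(ch$vmg, 0)
  }
})

test_that("position stepping is great-circle displacement", {
  # identity under zero velocity
  p <- step_position(-17, 210, 0, 0, 6)
  expect_equal(c(p$lat, p$lon), c(-17, 210))
  # 1 m/s due north for 24 h from (0, 210): +86.4 km = +0.7771 deg lat
  p <- step_position(0, 210, 0, 1, 24)
  expect_equal(p$lon, 210, tolerance = 1e-9)
  expect_equal(p$lat, (86400 / 6371000) * 180 / pi, tolerance = 1e-9)
  expect_equal(p$lat, 0.777, tolerance = 1e-3)
  # eastward step across the dateline wraps with no distance discontinuity
  p <- step_position(-20, 179.9, 5, 0, 24)
  expect_gt(p$lon, 180)
  d1 <- gc_distance(-20, 179.9, -20, 185)
  d2 <- gc_distance(p$lat, p$lon, -20, 185)
  expect_lt(d2, d1)
})

test_that("a static world strands the vessel where it started", {
  fs <- const_fieldset(wind_u = 0, wind_v = 0, cur_u = 0, cur_v = 0)
  trip <- simulate_trip(0, "hawaii", fs, vessel_polar(),
                        sim_config(max_duration = 10, heading_noise_sd = 0))
  expect_equal(trip$outcome, "timed_out")
  expect_equal(unique(trip$points$lat), route_points()$tahiti[["lat"]])
  expect_equal(unique(trip$points$lon), route_points()$tahiti[["lon"]])
  expect_equal(trip$duration_days, 10)
})

test_that("a uniform current to a 1000-km target arrives in ~5.8 days", {
  # target due north of the start, pure drift at 2 m/s northward
  start <- c(lat = 0, lon = 200)
  tgt_lat <- (1e6 / 6371000) * 180 / pi   # 1000 km north
  targets <- list(test = c(lat = tgt_lat, lon = 200))
  fs <- const_fieldset(cur_v = 2)
  # radius 25 km: comparable to the 43-km displacement of one 6-h step
  trip <- simulate_trip(0, "test", fs, vessel_polar(),
                        sim_config(heading_noise_sd = 0, arrival_radius = 25),
                        start = start, targets = targets)
  expect_equal(trip$outcome, "arrived")
  # 1000 km / 2 m/s = 5.787 days, one 6-h step of slack either way
  expect_equal(trip$duration_days, 1e6 / 2 / 86400, tolerance = 0.25 / 5.787)
})

test_that("zero wind reduces the trajectory to pure drift", {
  fs <- const_fieldset(cur_u = 0.5, cur_v = 0.2)
  trip <- simulate_trip(0, "hawaii", fs, vessel_polar(),
                        sim_config(max_duration = 5, heading_noise_sd = 0))
  expect_true(all(trip$points$sail_u == 0 & trip$points$sail_v == 0))
  # independent integration of the drift
  pos <- as.list(route_points()$tahiti)
  for (i in seq_len(nrow(trip$points) - 1)) {
    pos <- step_position(pos$lat, pos$lon, 0.5, 0.2, 6)
  }
  n <- nrow(trip$points)
  expect_equal(trip$points$lat[n], pos$lat, tolerance = 1e-9)
  expect_equal(trip$points$lon[n], pos$lon, tolerance = 1e-9)
})

test_that("trips are deterministic and respect the 50-day cap", {
  fs <- tiny_fieldset(seed = 41, days = 60, resolution = 5)
  t1 <- simulate_trip(0, "hawaii", fs, vessel_polar(), sim_config(),
                      vessel = 3, seed = 9)
  t2 <- simulate_trip(0, "hawaii", fs, vessel_polar(), sim_config(),
                      vessel = 3, seed = 9)
  expect_identical(t1$points, t2$points)
  expect_lte(t1$duration_days, 50)
  t3 <- simulate_trip(0, "hawaii", fs, vessel_polar(), sim_config(),
                      vessel = 4, seed = 9)
  expect_false(identical(t1$points, t3$points))  # vessels differ by noise
})

test_that("arrived trips end within the arrival radius", {
  fs <- const_fieldset(cur_v = 2)
  tgt_lat <- (1e6 / 6371000) * 180 / pi
  trip <- simulate_trip(0, "test", fs, vessel_polar(),
                        sim_config(heading_noise_sd = 0, arrival_radius = 30),
                        start = c(lat = 0, lon = 200),
                        targets = list(test = c(lat = tgt_lat, lon = 200)))
  n <- nrow(trip$points)
  expect_equal(trip$outcome, "arrived")
  expect_lte(gc_distance(trip$points$lat[n], trip$points$lon[n],
                         tgt_lat, 200), 30 * 1000)
})

test_that("leaving the domain terminates the trip", {
  fs <- const_fieldset(cur_u = -2, lat = seq(-25, -10, 5),
                       lon = seq(200, 220, 5))
  trip <- simulate_trip(0, "hawaii", fs, vessel_polar(),
                        sim_config(heading_noise_sd = 0))
  expect_equal(trip$outcome, "exited_domain")
  expect_error(simulate_trip(0, "hawaii", fs, vessel_polar(), sim_config(),
                             start = c(lat = 5, lon = 210)),
               "configuration error")
})

test_that("the departure schedule matches the stated arithmetic", {
  cfg <- sim_config()
  s1 <- schedule_departures(cfg, 1)
  expect_equal(sum(s1$destination == "hawaii"), 73 * 8)
  expect_equal(sum(s1$destination == "new_zealand"), 73 * 8)
  s3 <- schedule_departures(cfg, 3)
  expect_equal(sum(s3$destination == "hawaii"), 1752)
  expect_equal(length(unique(s3$departure_day)), 73)
  s0 <- schedule_departures(cfg, 0)
  expect_equal(nrow(s0), 0)
})

test_that("trip CSV carries metadata and the point table", {
  fs <- const_fieldset(cur_v = 1)
  trip <- simulate_trip(0, "hawaii", fs, vessel_polar(),
                        sim_config(max_duration = 2, heading_noise_sd = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trip_csv(trip, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# destination: hawaii", lines)))
  expect_true(any(grepl("^# outcome:", lines)))
  tab <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(tab), nrow(trip$points))
})
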