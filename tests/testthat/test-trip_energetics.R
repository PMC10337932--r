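# Departure-day aggregation and statistics

test_that("vessel-mean environment of identical trips equals any member", {
  fs <- const_fieldset(ta = 22, wind_u = -5, solar = 300)
  trips <- replicate(8, fake_trip(seq(-17, -13, by = 0.5),
                                  rep(210, 9)), simplify = FALSE)
  denv <- departure_env(trips, fs)
  expect_equal(denv$n_vessels, 8)
  expect_true(all(denv$env$n_vessels == 8))
  expect_true(all(abs(denv$env$ta - 22) < 1e-9))
  expect_true(all(abs(denv$env$ws1p5 - adjust_wind(5)) < 1e-9))
  expect_true(all(abs(denv$env$solar - 300) < 1e-9))
})

test_that("vessel means match a brute-force per-hour average", {
  fs <- tiny_fieldset(seed = 51, days = 6, resolution = 5)
  set.seed(3)
  trips <- lapply(1:3, function(v) {
    fake_trip(seq(-17.5, -10, length.out = 13) + rnorm(13, 0, 0.2),
              seq(210, 205, length.out = 13) + rnorm(13, 0, 0.2),
              vessel = v)
  })
  denv <- departure_env(trips, fs)
  hours <- denv$env$t
  # independent oracle: per-vessel hourly positions + field sampling
  manual <- sapply(hours, function(h) {
    vals <- sapply(trips, function(tr) {
      la <- stats::approx(tr$points$t, tr$points$lat, xout = h)$y
      lo <- stats::approx(tr$points$t, tr$points$lon, xout = h)$y
      brute_interp(fs$time_atmos, fs$lat, fs$lon, fs$sat, h, la, lo)
    })
    mean(vals)
  })
  expect_equal(denv$env$ta, manual, tolerance = 1e-9)
})

test_that("unequal durations: en-route averaging vs shortest truncation", {
  fs <- const_fieldset(ta = 20)
  short <- fake_trip(seq(-17, -16, by = 0.5), rep(210, 3))     # 12 h
  long <- fake_trip(seq(-17, -13, by = 0.5), rep(210, 9))      # 48 h
  denv <- departure_env(list(short, long), fs)
  expect_equal(max(denv$env$t), 48)
  expect_equal(denv$truncation_hours, 12)
  expect_equal(denv$env$n_vessels[denv$env$t <= 12], rep(2, 13))
  expect_equal(denv$env$n_vessels[denv$env$t > 12], rep(1, 36))
  denv2 <- departure_env(list(short, long), fs, truncate = "shortest")
  expect_equal(max(denv2$env$t), 12)
})

test_that("mixed departures are rejected", {
  fs <- const_fieldset()
  a <- fake_trip(c(-17, -16), c(210, 210), departure_hours = 0)
  b <- fake_trip(c(-17, -16), c(210, 210), departure_hours = 24)
  expect_error(departure_env(list(a, b), fs), "share departure")
  expect_error(departure_env(list(), fs))
})

test_that("two-vessel temperature averaging is the arithmetic mean", {
  # vessels pinned to nodes held at 20 and 24 degC
  fs <- const_fieldset(ta = 20)
  fs$sat[, 3, ] <- 24   # the latitude row vessel 2 sits on
  v1 <- fake_trip(rep(fs$lat[2], 5), rep(200, 5))
  v2 <- fake_trip(rep(fs$lat[3], 5), rep(200, 5))
  denv <- departure_env(list(v1, v2), fs)
  expect_true(all(abs(denv$env$ta - 22) < 1e-9))
})

test_that("eb_series unit bookkeeping matches the closed-form conversion", {
  # constant EB of -100 W over 24 h -> aEB = -100 * 86400 / 4184 kcal
  body <- std_body()
  ex <- std_exposure()
  # choose Ta so EB == -100 exactly: solve for the driving difference
  r0 <- heat_loss(body, ex, 0, 3, 0)
  base_per_K <- (r0$Ld + r0$Lw) / (ex$Tc - 273.15)
  ta <- ex$Tc - 273.15 - (r0$bmr + 100) / base_per_K
  denv <- structure(list(
    env = data.frame(t = 0:23, ta = ta, ws1p5 = 3, solar = 0),
    departure_hours = 0, departure_day = 1, year = 1,
    destination = "hawaii", n_vessels = 8, truncation_hours = 24),
    class = "departure_env")
  s <- eb_series(denv, body, ex)
  expect_equal(s$hourly$EB, rep(-100, 24), tolerance = 1e-9)
  expect_equal(s$aEB, -100 * 24 * 3600 / 4184, tolerance = 1e-9)
  expect_equal(s$aEB, -2065.0, tolerance = 1e-4)
  expect_equal(s$mean_daily_eb, s$aEB)   # 1-day series
  # 1 W sustained for a day is 20.65 kcal/day, to 0.1%
  expect_equal(abs(s$mean_daily_eb) / 100, 20.65, tolerance = 1e-3)
  # doubling series length doubles aEB
  denv2 <- denv; denv2$env <- rbind(denv$env, transform(denv$env, t = t + 24))
  s2 <- eb_series(denv2, body, ex)
  expect_equal(s2$aEB, 2 * s$aEB, tolerance = 1e-9)
  expect_equal(s2$mean_daily_eb, s$mean_daily_eb, tolerance = 1e-9)
  # EB identically zero integrates to zero
  denv0 <- denv
  denv0$env$ta <- ex$Tc - 273.15 - r0$bmr / base_per_K
  s0 <- eb_series(denv0, body, ex)
  expect_equal(s0$hourly$EB, rep(0, 24), tolerance = 1e-9)
  expect_equal(s0$aEB, 0, tolerance = 1e-9)
})

test_that("departure-day statistics give the closed-form t interval", {
  tab <- data.frame(departure_day = rep(1, 3), year = 1:3,
                    destination = "hawaii", body = "B1", sex = "female",
                    exposure = "Hhl", aEB = 0,
                    mean_daily_eb = c(-100, -120, -140), duration_days = 25)
  st <- departure_day_stats(tab)
  expect_equal(st$mean, -120)
  expect_equal(st$ci_half_width, qt(0.975, 2) * 20 / sqrt(3), tolerance = 1e-9)
  expect_equal(st$ci_half_width, 49.68, tolerance = 1e-3)
  # identical values give a zero-width interval
  tab$mean_daily_eb <- rep(-100, 3)
  expect_equal(departure_day_stats(tab)$ci_half_width, 0)
  # grouping respects departure day
  tab2 <- tab
  tab2$departure_day <- c(1, 1, 6)
  st2 <- departure_day_stats(tab2)
  expect_equal(st2$n, c(2, 1))
})

test_that("seasonal means partition and recompose the annual mean", {
  days <- seq(1, 365, by = 5)
  st <- data.frame(departure_day = days, n = 3,
                   mean = sin(days / 58) * 100, ci_half_width = 1,
                   season = season_of_doy(days))
  sm <- seasonal_means(st)
  expect_equal(sum(sm$n_days), length(days))
  expect_equal(sum(sm$mean * sm$n_days) / sum(sm$n_days), mean(st$mean),
               tolerance = 1e-9)
  # constant series: every seasonal mean equals it
  st$mean <- -42
  expect_true(all(seasonal_means(st)$mean == -42))
})

test_that("welch contrast matches t.test and handles degeneracy", {
  set.seed(61)
  for (k in 1:20) {
    x <- rnorm(sample(3:12, 1), 0, runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), 1, runif(1, 0.5, 3))
    w <- welch_contrast(x, y)
    tt <- t.test(x, y)   # Welch by default
    expect_equal(w$diff, unname(diff(rev(tt$estimate))), tolerance = 1e-9)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-9)
    expect_equal(w$ci_half_width, unname(diff(tt$conf.int)) / 2,
                 tolerance = 1e-9)
    expect_equal(w$significant, tt$p.value < 0.05)
  }
  # degenerate zero-variance case: exact difference
  w <- welch_contrast(c(-10, -10, -10), c(-20, -20, -20))
  expect_equal(w$diff, 10)
  expect_equal(w$ci_half_width, 0)
  expect_true(w$significant)
  w0 <- welch_contrast(c(-10, -10), c(-10, -10))
  expect_false(w0$significant)
})

test_that("destination contrast is per matched departure day", {
  mk <- function(dest, shift) {
    expand.grid(departure_day = c(1, 50), year = 1:3, body = "B1",
                sex = "female", exposure = "Hhl",
                destination = dest, stringsAsFactors = FALSE) |>
      transform(aEB = 0, duration_days = 25,
                mean_daily_eb = -100 - shift + c(-1, 0, 1))
  }
  ct <- destination_contrast(mk("new_zealand", 50), mk("hawaii", 0))
  expect_equal(ct$departure_day, c(1, 50))
  expect_equal(ct$diff, c(-50, -50), tolerance = 1e-9)
  expect_true(all(ct$significant))
  # identical groups: no difference, not significant
  ct0 <- destination_contrast(mk("new_zealand", 0), mk("hawaii", 0))
  expect_equal(ct0$diff, c(0, 0), tolerance = 1e-12)
  expect_false(any(ct0$significant))
})

test_that("aEB ratios are per grouping with a min-max range", {
  tab <- expand.grid(departure_day = 1, year = 1, body = c("B1", "B2"),
                     sex = "female", exposure = c("Hhl", "Lhl"),
                     destination = c("new_zealand", "hawaii"),
                     stringsAsFactors = FALSE)
  tab$mean_daily_eb <- 0; tab$duration_days <- 25
  tab$aEB <- ifelse(tab$destination == "new_zealand", -3300, -1000)
  tab$aEB[tab$destination == "new_zealand" & tab$body == "B2"] <- -4800
  r <- aeb_ratio(tab)
  expect_equal(sort(unique(r$by_group$ratio)), c(3.3, 4.8))
  expect_equal(r$range, c(3.3, 4.8))
  # invariance under common rescaling
  tab2 <- tab; tab2$aEB <- tab2$aEB * 7.5
  expect_equal(aeb_ratio(tab2)$range, r$range, tolerance = 1e-12)
})
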