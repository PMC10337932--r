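#' @title Trip-level energetics
#'
#' @description
#' Combines simulated trips with the resting energy-balance model. The
#' environmental forcing for a departure day is the hourly mean of the
#' conditions experienced by the eight vessels of that departure and
#' destination (so results are per departure day, not per vessel); the EB
#' model is then applied hour by hour for each body type and exposure
#' scenario, summed over the voyage into an aggregate EB (aEB, kcal), and
#' summarised into departure-day means with t-based 95% confidence
#' intervals, seasonal means, destination contrasts (Welch) and aEB ratios.
#'
#' @name trip_energetics
NULL

KCAL_PER_JOULE <- 1 / 4184

#' Hourly vessel-mean environment for one departure
#'
#' Interpolates every vessel's position to an hourly grid, samples the
#' fields there, adjusts wind to 1.5 m, and averages across the vessels
#' still en route at each hour. By default the series extends to the
#' latest member endpoint (`truncate = "none"`, all data used); with
#' `truncate = "shortest"` it is cut at the earliest member endpoint.
#'
#' @param trips list of `eb_trip`s sharing departure time and destination.
#' @param fieldset the `env_fieldset` the trips were simulated in.
#' @param truncate `"none"` or `"shortest"`.
#' @return an object of class `departure_env`: data.frame `env` (`t`, `ta`,
#'   `ws1p5`, `solar`, `n_vessels`), plus `departure_hours`,
#'   `departure_day`, `year`, `destination`, `n_vessels`,
#'   `truncation_hours` (shortest member duration).
#' @export
departure_env <- function(trips, fieldset, truncate = c("none", "shortest")) {
  truncate <- match.arg(truncate)
  stopifnot(length(trips) > 0)
  dep <- unique(vapply(trips, `[[`, numeric(1), "departure_hours"))
  dst <- unique(vapply(trips, `[[`, character(1), "destination"))
  if (length(dep) != 1 || length(dst) != 1) {
    stop("trips must share departure time and destination", call. = FALSE)
  }
  ends <- vapply(trips, function(tr) max(tr$points$t), numeric(1))
  t_stop <- if (truncate == "shortest") min(ends) else max(ends)
  hours <- seq(dep, t_stop, by = 1)

  acc_ta <- acc_ws <- acc_s <- matrix(NA_real_, nrow = length(hours),
                                      ncol = length(trips))
  for (j in seq_along(trips)) {
    p <- trips[[j]]$points
    sel <- hours <= max(p$t)
    if (!any(sel)) next
    hj <- hours[sel]
    # positions linear in time between 6-h trajectory points; longitudes in
    # 0-360 so tracks crossing 180 interpolate without a jump
    latj <- stats::approx(p$t, p$lat, xout = hj, rule = 2)$y
    lonj <- stats::approx(p$t, p$lon, xout = hj, rule = 2)$y
    env <- sample_env(fieldset, latj, lonj, hj)
    acc_ta[sel, j] <- env$ta
    acc_ws[sel, j] <- adjust_wind(env$ws10)
    acc_s[sel, j] <- env$solar
  }
  n_vessels <- rowSums(!is.na(acc_ta))
  keep <- n_vessels > 0
  env <- data.frame(t = hours[keep],
                    ta = rowMeans(acc_ta, na.rm = TRUE)[keep],
                    ws1p5 = rowMeans(acc_ws, na.rm = TRUE)[keep],
                    solar = rowMeans(acc_s, na.rm = TRUE)[keep],
                    n_vessels = n_vessels[keep])
  structure(list(env = env, departure_hours = dep,
                 departure_day = trips[[1]]$departure_day,
                 year = trips[[1]]$year, destination = dst,
                 n_vessels = length(trips),
                 truncation_hours = min(ends) - dep),
            class = "departure_env")
}

#' Hourly EB series and voyage aggregate for one body/exposure
#'
#' Applies the resting energy-balance model at every hour of a departure's
#' vessel-mean environment, then integrates: aEB is the left-rectangle sum
#' of the hourly EB rates (W) over the series, converted to kcal
#' (3600 J per W-hour / 4184 J per kcal); `mean_daily_eb` divides by the
#' series length in days.
#'
#' @param denv a [departure_env()].
#' @param body a [body_type()].
#' @param exposure an [exposure_params()].
#' @return an object of class `eb_series`: data.frame `hourly` (`t`, `EB`
#'   and components, W), `aEB` (kcal), `mean_daily_eb` (kcal/day),
#'   `duration_days`, plus body/exposure/departure metadata.
#' @export
eb_series <- function(denv, body, exposure) {
  stopifnot(inherits(denv, "departure_env"))
  res <- eb(body, exposure, denv$env$ta, denv$env$ws1p5, denv$env$solar)
  res$t <- denv$env$t
  aEB <- sum(res$EB) * 3600 * KCAL_PER_JOULE
  dur <- nrow(res) / 24
  structure(list(hourly = res, aEB = aEB, mean_daily_eb = aEB / dur,
                 duration_days = dur, body = body$label, sex = body$sex,
                 exposure = exposure$label,
                 departure_day = denv$departure_day, year = denv$year,
                 destination = denv$destination),
            class = "eb_series")
}

#' Flatten EB series into a tidy table
#'
#' @param series list of [eb_series()] objects.
#' @return data.frame with one row per series: `departure_day`, `year`,
#'   `destination`, `body`, `sex`, `exposure`, `aEB` (kcal),
#'   `mean_daily_eb` (kcal/day), `duration_days`.
#' @export
series_table <- function(series) {
  do.call(rbind, lapply(series, function(s) {
    data.frame(departure_day = s$departure_day, year = s$year,
               destination = s$destination, body = s$body, sex = s$sex,
               exposure = s$exposure, aEB = s$aEB,
               mean_daily_eb = s$mean_daily_eb,
               duration_days = s$duration_days)
  }))
}

#' Departure-day mean and 95% confidence interval
#'
#' Groups a tidy series table by departure day (pooling whatever
#' years/bodies/exposures are present in each group) and returns the group
#' mean of `mean_daily_eb` with a Student-t 95% CI of the mean. Groups of
#' size one get an NA half-width.
#'
#' @param tab data.frame from [series_table()] (optionally pre-filtered).
#' @param value column to summarise (default `"mean_daily_eb"`).
#' @return data.frame: `departure_day`, `n`, `mean`, `ci_half_width`,
#'   `season`.
#' @export
departure_day_stats <- function(tab, value = "mean_daily_eb") {
  days <- sort(unique(tab$departure_day))
  out <- lapply(days, function(d) {
    x <- tab[[value]][tab$departure_day == d]
    n <- length(x)
    hw <- if (n >= 2) {
      s <- stats::sd(x)
      stats::qt(0.975, n - 1) * s / sqrt(n)
    } else NA_real_
    data.frame(departure_day = d, n = n, mean = mean(x), ci_half_width = hw)
  })
  out <- do.call(rbind, out)
  out$season <- season_of_doy(out$departure_day)
  out
}

#' Seasonal means of a departure-day series
#'
#' Means over departure days within each meteorological season
#' (southern-hemisphere convention: DJF is summer). The season partition
#' covers the whole year, so day-weighted seasonal means recompose the
#' annual mean.
#'
#' @param day_stats data.frame from [departure_day_stats()].
#' @return data.frame: `season`, `n_days`, `mean`.
#' @export
seasonal_means <- function(day_stats) {
  seasons <- levels(day_stats$season)
  do.call(rbind, lapply(seasons, function(s) {
    x <- day_stats$mean[day_stats$season == s]
    data.frame(season = s, n_days = length(x),
               mean = if (length(x)) mean(x) else NA_real_)
  }))
}

#' Welch two-sample comparison
#'
#' Difference of means with a Welch (unequal-variance) 95% CI. The
#' degenerate zero-variance case is handled exactly: zero half-width,
#' significant iff the difference is nonzero.
#'
#' @param x,y numeric samples.
#' @return list: `diff` (mean(x) - mean(y)), `ci_half_width`, `df`,
#'   `significant` (CI excludes 0).
#' @export
welch_contrast <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  d <- mean(x) - mean(y)
  vx <- if (nx > 1) stats::var(x) else 0
  vy <- if (ny > 1) stats::var(y) else 0
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    return(list(diff = d, ci_half_width = 0, df = NA_real_,
                significant = d != 0))
  }
  df <- se2^2 / ((vx / nx)^2 / max(nx - 1, 1) + (vy / ny)^2 / max(ny - 1, 1))
  hw <- stats::qt(0.975, df) * sqrt(se2)
  list(diff = d, ci_half_width = hw, df = df, significant = abs(d) > hw)
}

#' Per-departure-day destination contrast
#'
#' For each departure day present in both tables, the NZ-minus-HW
#' difference of `mean_daily_eb` means with a Welch 95% CI, pooling the
#' matched configurations (years/bodies/exposures) in each group.
#'
#' @param nz_tab,hw_tab tidy tables from [series_table()] for the two
#'   destinations, already filtered to matched body/exposure
#'   configurations.
#' @return data.frame: `departure_day`, `diff` (kcal/day),
#'   `ci_half_width`, `significant`, `season`.
#' @export
destination_contrast <- function(nz_tab, hw_tab) {
  days <- intersect(unique(nz_tab$departure_day), unique(hw_tab$departure_day))
  out <- do.call(rbind, lapply(sort(days), function(d) {
    w <- welch_contrast(nz_tab$mean_daily_eb[nz_tab$departure_day == d],
                        hw_tab$mean_daily_eb[hw_tab$departure_day == d])
    data.frame(departure_day = d, diff = w$diff,
               ci_half_width = w$ci_half_width, significant = w$significant)
  }))
  out$season <- season_of_doy(out$departure_day)
  out
}

#' Aggregate-EB ratio between destinations
#'
#' `|mean aEB(NZ)| / |mean aEB(HW)|` per body-and-exposure grouping, plus
#' the min--max range across groupings.
#'
#' @param tab tidy table from [series_table()] containing both
#'   destinations.
#' @param nz,hw destination names.
#' @return list: `by_group` (data.frame `body`, `sex`, `exposure`,
#'   `ratio`), `range` (`c(min, max)`), `overall` (ratio of overall
#'   means).
#' @export
aeb_ratio <- function(tab, nz = "new_zealand", hw = "hawaii") {
  groups <- unique(tab[, c("body", "sex", "exposure")])
  by_group <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- tab$body == g$body & tab$sex == g$sex & tab$exposure == g$exposure
    m_nz <- mean(tab$aEB[sel & tab$destination == nz])
    m_hw <- mean(tab$aEB[sel & tab$destination == hw])
    if (m_nz == 0 || m_hw == 0) {
      stop("aEB aggregates must be nonzero", call. = FALSE)
    }
    data.frame(body = g$body, sex = g$sex, exposure = g$exposure,
               ratio = abs(m_nz) / abs(m_hw))
  }))
  overall <- abs(mean(tab$aEB[tab$destination == nz])) /
    abs(mean(tab$aEB[tab$destination == hw]))
  list(by_group = by_group, range = range(by_group$ratio), overall = overall)
}
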