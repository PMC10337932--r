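#' @title Worked-example conversions
#'
#' @description
#' Translates a daily thermoregulatory energy deficit (kcal/day) into
#' equivalent quantities: fat or muscle mass consumed, extra food required,
#' and the physical activity needed to generate the same heat. These are
#' linear unit conversions, not metabolic models; energy densities are
#' configuration values with USDA-consistent defaults.
#'
#' @name interpretation
NULL

#' Energy-density table
#'
#' @param fat fat energy density, kcal/g (default 9).
#' @param muscle muscle energy density, kcal/g (default 4).
#' @param foods named vector of food energy densities, kcal/g.
#' @return an object of class `energy_density_table`.
#' @export
energy_density_table <- function(fat = 9, muscle = 4,
                                 foods = c(fish = 1.00, cooked_taro = 1.42,
                                           boiled_breadfruit_seeds = 1.68)) {
  stopifnot(fat > 0, muscle > 0, all(foods > 0))
  structure(list(fat = fat, muscle = muscle, foods = foods),
            class = "energy_density_table")
}

#' Fat-mass equivalent of a daily deficit
#'
#' @param deficit daily energy deficit, kcal/day (>= 0).
#' @param days trip duration, days.
#' @param table an [energy_density_table()].
#' @return list: `g_per_day` (1 decimal place), `kg_total` (2 d.p.).
#' @export
fat_equivalent <- function(deficit, days, table = energy_density_table()) {
  stopifnot(deficit >= 0, days >= 0)
  g_day <- round(deficit / table$fat, 1)
  list(g_per_day = g_day, kg_total = round(g_day * days / 1000, 2))
}

#' Muscle-mass equivalent of a daily deficit
#'
#' @inheritParams fat_equivalent
#' @return total muscle mass in kg (2 d.p.).
#' @export
muscle_equivalent <- function(deficit, days, table = energy_density_table()) {
  stopifnot(deficit >= 0, days >= 0)
  round(deficit * days / table$muscle / 1000, 2)
}

#' Food-mass equivalent of a daily deficit
#'
#' @inheritParams fat_equivalent
#' @param food name of a food in the table.
#' @return daily food mass in grams (nearest gram).
#' @export
food_equivalent <- function(deficit, food, table = energy_density_table()) {
  stopifnot(deficit >= 0)
  if (!food %in% names(table$foods)) {
    stop("unknown food: '", food, "' (have: ",
         paste(names(table$foods), collapse = ", "), ")", call. = FALSE)
  }
  round(deficit / table$foods[[food]])
}

#' Physical-activity equivalent of a daily deficit
#'
#' Only a fraction of calories spent on physical activity end up heating
#' the body (~11.6% near 12 degC), so covering a deficit through activity
#' alone requires `deficit / heat_fraction` kcal/day of activity.
#'
#' @inheritParams fat_equivalent
#' @param heat_fraction fraction of activity calories converted to body
#'   heat, in `(0, 1]`.
#' @return activity expenditure in kcal/day (nearest kcal). With the
#'   default inputs of the documented worked example (965 kcal/day, 0.116)
#'   this computes 8319 kcal/day.
#' @export
activity_equivalent <- function(deficit, heat_fraction = 0.116) {
  stopifnot(deficit >= 0, heat_fraction > 0, heat_fraction <= 1)
  round(deficit / heat_fraction)
}

#' Full interpretation report
#'
#' @inheritParams fat_equivalent
#' @param heat_fraction see [activity_equivalent()].
#' @return nested list with all conversions (suitable for JSON output).
#' @export
interpret_deficit <- function(deficit, days, table = energy_density_table(),
                              heat_fraction = 0.116) {
  fat <- fat_equivalent(deficit, days, table)
  foods <- vapply(names(table$foods),
                  function(f) food_equivalent(deficit, f, table), numeric(1))
  list(deficit_kcal_day = deficit, days = days,
       fat_g_per_day = fat$g_per_day, fat_kg_total = fat$kg_total,
       muscle_kg_total = muscle_equivalent(deficit, days, table),
       food_g_per_day = as.list(foods),
       activity_kcal_day = activity_equivalent(deficit, heat_fraction))
}
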