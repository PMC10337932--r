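#' @title Resting energy balance
#'
#' @description
#' The resting energy balance of a traveller is `EB = BMR - L` (watts),
#' where `L = Ld + Lw - Sa` is net heat loss: `Ld` and `Lw` are
#' radiative/conductive/convective losses over the dry and wet body
#' fractions, and `Sa` is absorbed shortwave radiation (a gain). The shared
#' driving term is `BSA * (Tc - Ta) / (R + 1/C)` with `R` the summed thermal
#' resistance of the insulating layers (subcutaneous fat, clothing), and
#' `C = 5 + 3.95 WS^0.6` the wind-dependent convective transfer coefficient
#' evaluated with wind adjusted from 10 m to deck height (1.5 m). Heat loss
#' over the wet fraction is increased by 50%.
#'
#' All temperature differences are computed in kelvin; ambient temperature
#' is supplied in degC and converted internally. `Ta > Tc` is allowed and
#' yields a negative "loss" (net heat gain) without clamping.
#'
#' @name energy_balance
NULL

#' Exposure parameter set
#'
#' Bundles the exposure fractions, skin albedo, core temperature and
#' insulating-layer properties for one heat-loss scenario.
#'
#' @param wfr time-average wet body fraction, in `[0, 1]`.
#' @param ifr illuminated (sunlit) body fraction, in `[0, 1]`.
#' @param cfr clothed body fraction, in `[0, 1]`.
#' @param alpha skin albedo (fraction of sunlight reflected), in `[0, 1]`.
#' @param Tc core temperature, K (default 310.15 K = 37 degC).
#' @param clothing_s clothing thickness, m (default 0.0012, bark cloth).
#' @param clothing_k clothing conductivity, W/mK (default 0.0357, bark cloth).
#' @param scf_k subcutaneous-fat conductivity, W/mK (default 0.2).
#' @param label scenario label (`"Hhl"` high heat loss, `"Lhl"` low).
#' @return an object of class `exposure_params`.
#' @export
exposure_params <- function(wfr, ifr, cfr, alpha, Tc = 310.15,
                            clothing_s = 0.0012, clothing_k = 0.0357,
                            scf_k = 0.2, label = "custom") {
  stopifnot(wfr >= 0, wfr <= 1, ifr >= 0, ifr <= 1, cfr >= 0, cfr <= 1,
            alpha >= 0, alpha <= 1, Tc > 273.15,
            clothing_s > 0, clothing_k > 0, scf_k > 0)
  structure(list(wfr = wfr, ifr = ifr, cfr = cfr, alpha = alpha, Tc = Tc,
                 clothing_s = clothing_s, clothing_k = clothing_k,
                 scf_k = scf_k, label = label), class = "exposure_params")
}

#' Default high/low heat-loss exposure scenarios
#'
#' Each parameter sits at the loss-maximising (Hhl) or loss-minimising
#' (Lhl) end of its design range: wet fraction 0.20/0.10, illuminated
#' fraction 0.3/0.4, clothed fraction 0.25/0.50, skin albedo 0.30/0.25.
#'
#' @return named list with `Hhl` and `Lhl` [exposure_params()].
#' @export
default_exposures <- function() {
  list(Hhl = exposure_params(wfr = 0.20, ifr = 0.3, cfr = 0.25, alpha = 0.30,
                             label = "Hhl"),
       Lhl = exposure_params(wfr = 0.10, ifr = 0.4, cfr = 0.50, alpha = 0.25,
                             label = "Lhl"))
}

#' Adjust wind speed between elevations
#'
#' Empirical power-law wind profile over the ocean:
#' `WS(z1) = WS(z) * (z1/z)^P`. The default maps 10-m reanalysis winds to
#' the 1.5-m elevation occupied by someone in a sailing canoe (always a
#' reduction for z1 < z).
#'
#' @param WS_z wind speed at elevation `z`, m/s (>= 0).
#' @param z source elevation, m (default 10).
#' @param z1 target elevation, m (default 1.5).
#' @param P profile exponent (default 0.11).
#' @return wind speed at `z1`, m/s.
#' @export
adjust_wind <- function(WS_z, z = 10, z1 = 1.5, P = 0.11) {
  stopifnot(all(WS_z >= 0), z > 0, z1 > 0)
  WS_z * (z1 / z)^P
}

#' Convective heat-transfer coefficient
#'
#' `C = 5 + 3.95 * WS^0.6` with WS the wind speed at 1.5 m. Dimensionally C
#' acts as a transfer coefficient (W/m^2 per kelvin of driving difference)
#' entering the loss expression as `1/C` in series with the insulation
#' resistance.
#'
#' @param WS wind speed at 1.5 m, m/s (>= 0).
#' @return transfer coefficient, W/m^2K.
#' @export
convection <- function(WS) {
  stopifnot(all(WS >= 0))
  5 + 3.95 * WS^0.6
}

#' Insulating layer
#'
#' @param s thickness, m (> 0).
#' @param k thermal conductivity, W/mK (> 0).
#' @param cfr fraction of the body covered, in `(0, 1]`.
#' @return a list usable by [thermal_resistance()].
#' @export
insulation_layer <- function(s, k, cfr = 1) {
  stopifnot(s > 0, k > 0, cfr > 0, cfr <= 1)
  list(s = s, k = k, cfr = cfr)
}

#' Total thermal resistance of insulating layers
#'
#' `R = sum_i (s_i / k_i) * cfr_i` in m^2K/W. Each layer contributes its
#' conductive resistance weighted by the covered body fraction; the limit
#' cfr -> 0 removes the layer.
#'
#' @param layers nonempty list of [insulation_layer()]s.
#' @return resistance, m^2K/W.
#' @export
thermal_resistance <- function(layers) {
  stopifnot(length(layers) > 0)
  sum(vapply(layers, function(l) (l$s / l$k) * l$cfr, numeric(1)))
}

# resistance of a body's SCF plus the scenario clothing layer
.body_resistance <- function(body, exposure) {
  layers <- list(insulation_layer(body$SCF, exposure$scf_k, 1))
  if (exposure$cfr > 0) {
    layers <- c(layers, list(insulation_layer(exposure$clothing_s,
                                              exposure$clothing_k,
                                              exposure$cfr)))
  }
  thermal_resistance(layers)
}

#' Absorbed shortwave radiation
#'
#' `Sa = BSA * ifr * S * (1 - alpha)`: the sunlit fraction of the body
#' surface absorbs the non-reflected part of the incoming flux.
#'
#' @param BSA body surface area, m^2.
#' @param ifr illuminated fraction, in `[0, 1]`.
#' @param S downward shortwave flux, W/m^2 (>= 0).
#' @param alpha skin albedo, in `[0, 1]`.
#' @return absorbed power, W.
#' @export
solar_absorption <- function(BSA, ifr, S, alpha) {
  stopifnot(all(S >= 0), ifr >= 0, ifr <= 1, alpha >= 0, alpha <= 1)
  BSA * ifr * S * (1 - alpha)
}

#' Heat-loss components for one body, exposure and environment
#'
#' @param body a [body_type()].
#' @param exposure an [exposure_params()].
#' @param ta_c ambient air temperature, degC (vector OK).
#' @param ws wind speed already adjusted to 1.5 m, m/s.
#' @param solar downward shortwave flux, W/m^2.
#' @return data.frame with columns `bmr`, `Ld`, `Lw`, `Sa`, `L`, `EB`
#'   (all watts), one row per environment sample.
#' @export
heat_loss <- function(body, exposure, ta_c, ws, solar) {
  stopifnot(inherits(body, "body_type"), inherits(exposure, "exposure_params"))
  n <- max(length(ta_c), length(ws), length(solar))
  ta_c <- rep_len(ta_c, n); ws <- rep_len(ws, n); solar <- rep_len(solar, n)
  BSA <- bsa(body$H, body$BM)
  R <- .body_resistance(body, exposure)
  C <- convection(ws)
  base <- BSA * (exposure$Tc - (ta_c + 273.15)) / (R + 1 / C)
  Ld <- (1 - exposure$wfr) * base
  Lw <- 1.5 * exposure$wfr * base
  Sa <- solar_absorption(BSA, exposure$ifr, solar, exposure$alpha)
  L <- Ld + Lw - Sa
  b <- bmr(body$sex, body$BM)
  data.frame(bmr = rep(b, n), Ld = Ld, Lw = Lw, Sa = Sa, L = L, EB = b - L)
}

#' Resting energy balance
#'
#' `EB = BMR - L` with all components populated; see [heat_loss()].
#'
#' @inheritParams heat_loss
#' @return data.frame as in [heat_loss()].
#' @export
eb <- function(body, exposure, ta_c, ws, solar) {
  heat_loss(body, exposure, ta_c, ws, solar)
}
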