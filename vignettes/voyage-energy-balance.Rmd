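---
title: "Thermoregulatory energy balance on simulated Pacific voyages: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermoregulatory energy balance on simulated Pacific voyages: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voyageEB)
```

## The question the package addresses

Long-distance canoe passages out of the tropics exposed Polynesian voyagers
to progressively colder air, stronger wind, and weaker sunshine. For a
resting traveller this shows up as an energy imbalance: heat flows out of
the body faster than resting metabolism produces it, and the difference has
to be paid in calories — body fat, muscle, extra food, or heat-generating
activity. `voyageEB` couples a drift-plus-sail voyage simulator to a
steady-state human heat-loss model so that this cost can be quantified and
contrasted between destinations (Tahiti to Hawaii versus Tahiti to
northern New Zealand), seasons, body types, and exposure assumptions.

All environmental forcing is synthetic: the generator produces gridded
fields with the climatological *structure* the analysis needs, so every
claim the package makes is comparative (NZ vs Hawaii, summer vs winter,
larger vs smaller bodies), never an absolute hindcast.

## The resting energy-balance model

The central quantity is the resting energy balance, in watts:

$$EB = BMR - L, \qquad L = L_d + L_w - S_a$$

* **BMR** comes from sex-specific linear ("Oxford"-style) equations in body
  mass $BM$ (kg): female $0.04843\,(13.1\,BM + 558)$, male
  $0.04843\,(16\,BM + 545)$, where $0.04843 = 4184/86400$ converts kcal/day
  to W.
* **Dry and wet loss** share the driving term
  $\mathrm{base} = BSA\,(T_c - T_a)/(R + 1/C)$:
  $L_d = (1-wfr)\cdot\mathrm{base}$ and $L_w = 1.5\,wfr\cdot\mathrm{base}$,
  i.e. the wet body fraction $wfr$ loses heat 50% faster.
* **Body surface area** is the power law
  $BSA = 0.024265\,H^{0.3964} BM^{0.5378}$ (H in cm).
* **Insulation** $R = \sum_i (s_i/k_i)\,cfr_i$ (m²K/W) sums subcutaneous
  fat (conductivity 0.2 W/mK, full coverage) and a bark-cloth clothing
  layer (s = 1.2 mm, k = 0.0357 W/mK, partial coverage $cfr$). The layer
  term must be $s/k$ on dimensional grounds; the package implements it that
  way.
* **Convection** $C = 5 + 3.95\,WS^{0.6}$ acts as a transfer coefficient
  (W/m²K) in series with $R$; the wind it sees is first moved from the
  10-m reference height to 1.5 m (deck height) with
  $WS_{1.5} = WS_{10}(1.5/10)^{0.11}$.
* **Solar gain** $S_a = BSA \cdot ifr \cdot S (1-\alpha)$ with illuminated
  fraction $ifr$ and skin albedo $\alpha$.

Temperatures are differenced in kelvin with core temperature
$T_c = 310.15\,$K; air warmer than the core produces a negative "loss"
(net gain) and is deliberately not clamped. Evaporative physiology beyond
the fixed 1.5× wet factor, shivering, and activity metabolism are out of
scope: this is a *resting* balance.

Two exposure scenarios bracket estimate uncertainty, each parameter at its
loss-maximising or loss-minimising end of the design range:

| scenario | wfr | ifr | cfr | albedo |
|----------|-----|-----|-----|--------|
| Hhl (high heat loss) | 0.20 | 0.3 | 0.25 | 0.30 |
| Lhl (low heat loss)  | 0.10 | 0.4 | 0.50 | 0.25 |

Whether solar absorption should be reduced over clothed skin is left
exactly as the equation above states (no clothing–illumination
interaction), and the 1.5× wet factor applies to the whole-body base term.

## Body types

Six bodies: per sex a baseline B1 and two derived types. B2 and B3 keep
B1's height and gain exactly two BMI units of mass; their subcutaneous-fat
thickness (SCF) is predicted from a linear BMI→SCF relation. The female
standard relation is steeper than the male one (female SCF more sensitive
to BMI); the "robustness" relations used for B3 flatten the female slope
and steepen the male slope. The baseline anthropometry (female 166 cm /
70 kg, male 175 cm / 80 kg, SCF 5 mm) and the four slope/intercept pairs
are **documented stand-ins**: the source anthropometric table and the
fitted athlete regressions are not published as numbers, so the package
ships config-overridable defaults that satisfy the stated *orderings*, and
its tests assert those orderings rather than any invented coefficient.
B1's SCF design range is 5–7.5 mm; both endpoints are exercised in tests.

## Synthetic environment

One simulated year is 365 days (no leap days), which matches the 73
five-day departure slots. Fields are deterministic functions of a seed:

* **SAT**: equator mean 27 °C decaying 0.45 °C per degree of latitude; a
  seasonal cycle growing linearly with |lat| up to a 6 °C amplitude at
  40°, peaking mid-January south of the equator and mid-July north of it;
  an ENSO SAT anomaly (±1.5 °C, eastern-equatorial pattern) for El Niño /
  La Niña years; smooth travelling-wave "weather" noise (sd 1 °C).
* **Wind**: easterly trade belts centred at ±14° (7 m/s, width 13°),
  westerlies at ±43–45° (9 m/s), equatorward meridional convergence, a
  westerly equatorial anomaly in El Niño years, and synoptic noise with a
  3 m/s standard deviation. Belt widths and noise were chosen once for
  realism (trades reaching ~25° with ~4 m/s variability); the first draft
  used narrower belts and produced an unrealistically wide becalmed zone.
* **Shortwave**: top-of-atmosphere geometry (declination by day of year,
  hour angle by local solar time) × 0.75 clear-sky transmittance ×
  (1 − cloud attenuation), with the attenuation enhanced in the ITCZ band
  and in the winter-hemisphere storm belt. Flux is zero at local night by
  construction.
* **Currents**: zonal bands (westward equatorial currents, an eastward
  countercurrent, a mid-latitude eastward drift), daily values held
  constant within each day when sampled — the sub-daily treatment of
  daily ocean data is unstated in the source design, so piecewise-constant
  was chosen and documented.

Sampling is bilinear in space and linear in time (exact at nodes);
longitudes use the 0–360 convention so tracks crossing 180° interpolate
continuously. Fields serialise to a CF-style JSON text container (variables
`sat`, `u10`, `v10`, `ssrd`, `uo`, `vo`; dims time/lat/lon; units
attributes, kelvin SAT converted on read): a NetCDF library is not
available in the target runtime, so the NetCDF *layout* is kept in a
plain-text carrier.

What the generator does **not** emulate: storms, waves, fronts, realistic
spatial correlation of cloud, ENSO dynamics (the anomaly is a fixed
pattern), or land. A green structural test therefore establishes that the
pipeline reproduces the *direction* of environmental contrasts, not any
absolute magnitude.

## Voyage simulation

Every 6 hours a vessel's displacement is the vector sum of the surface
current and a sailing velocity. The sailing speed is wind speed times a
polar ratio at the true-wind angle off the heading, capped at 5 m/s. The
replica-canoe polar behind the original analysis is unpublished; the
default is a parametric stand-in (zero inside 45° of the wind, 0.35 at
90°, 0.45 at 135°, 0.40 at 180°) and everything downstream treats it as
configuration. Headings maximise velocity made good (sailing + current)
toward the great-circle bearing to the target over a ±60° fan in 5° steps,
ties broken toward the bearing and then the smaller compass angle. The
eight vessels of one departure differ only by seeded per-step heading
noise (sd 5°), the one mechanism documented for the unstated vessel
differentiation. Trips end on arrival (within 50 km by default), at 50
days, or on leaving the field domain (no environment is fabricated outside
it). Departures leave Tahiti every 5 days, eight vessels per destination,
toward fixed target points on southern Hawai'i and the NE coast of
Te Ika-a-Māui.

With this stand-in polar and synthetic winds, typical simulated durations
are ~35 days to Hawaii and ~45–50 to New Zealand — longer than the
reference durations under real forcing, mostly because the parametric
polar points poorly upwind. Durations are not a claim of the package.

## Aggregation

EB is evaluated on the hourly vessel-mean environment of each departure
day (positions interpolated hourly, fields sampled, wind adjusted to
1.5 m, then averaged across vessels still en route; the alternative of
truncating at the earliest arrival is a switch). Hourly EB rates are
summed (left-rectangle) into the voyage aggregate aEB (kcal;
1 W sustained for a day is 20.65 kcal/day) and normalised to kcal/day.
Departure-day means carry Student-t 95% confidence intervals;
destination differences use Welch intervals with exact handling of the
zero-variance degenerate case; seasons are meteorological
southern-hemisphere seasons assigned by departure date. Note the labelling
consequence: a late-November departure spends most of its voyage in
austral summer but counts as SON, which is why the seasonal summary — not
a single-day minimum — is the right place to read the summer minimum of
the NZ−HW gap.

## Worked-example conversions

A daily deficit converts linearly into fat (9 kcal/g), muscle (4 kcal/g),
food (fish 1.00, cooked taro 1.42, boiled breadfruit seeds 1.68 kcal/g;
USDA-consistent, configurable) and activity equivalents (11.6% of activity
calories become body heat near 12 °C, so the activity requirement is
deficit/0.116). Rounding follows the conventions of the published example
(0.1 g/day, 0.01 kg, nearest gram). One deliberate non-agreement: for a
965 kcal/day deficit the package computes 965/0.116 = **8319** kcal/day of
activity; the published figure is 8,310. The computed value is reported
as-is.

## Numerical and design choices

* 365-day calendar, hours as the time coordinate; seeds fix everything.
* Sphere of radius 6371 km; great-circle stepping and bearings.
* The 10 m → 1.5 m wind factor is $(z_1/z)^{0.11}$ (a reduction); the
  inline rendering of the source formula reads as an increase, which
  contradicts its own stated purpose and is treated as a typesetting loss.
* Demo profile (used by the structural acceptance test): 3° grid, one
  neutral year, departures every 15 days, 6-hourly atmosphere with hourly
  EB sampling by interpolation. This is a compute-budget scaling; the full
  profile (three ENSO years, 5-day departures, 1752 trips per destination)
  uses the same code paths.
* Group sizes below two return NA confidence intervals rather than
  fabricating a width.

## Known limitations

Absolute kcal values depend entirely on the synthetic climate and the
stand-in polar/anthropometry, and are not comparable to estimates driven
by reanalysis data. The heat-loss model is steady-state and resting; it
has no evaporation model, no radiative sky term separate from the bulk
coefficient, and no behavioural adaptation. Navigation is a greedy VMG
rule, which systematically under-performs offshore routing when a beam
wind pushes the boat past its target's longitude.

## A worked run

```{r demo, eval = FALSE}
cfg <- run_config("demo", seed = 1, output_dir = "voyageEB-demo")
res <- run_pipeline(cfg, progress = TRUE)
res$seasonal_gap          # NZ extra daily demand by season, kcal/day
res$ratios$range          # aEB ratio range across body/exposure groups
interpret_deficit(965, 25)
```
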