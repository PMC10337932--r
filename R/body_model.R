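#' @title Body types and anthropometry
#'
#' @description
#' Constructs the six body types used by the analysis (three per sex) and
#' the anthropometric quantities the energy-balance model consumes: body
#' mass index (BMI), body surface area (BSA), subcutaneous-fat thickness
#' (SCF) and basal metabolic rate (BMR, sex-specific "Oxford"-style linear
#' equations in body mass).
#'
#' The baseline (B1) anthropometry and the BMI-to-SCF regression
#' coefficients are configuration values: the shipped defaults are
#' representative stand-ins (documented in the package vignette), not fitted
#' estimates, and every downstream result is a function of the supplied
#' configuration.
#'
#' @name body_model
NULL

#' kcal/day to watts conversion factor
#'
#' Computed analytically: 4184 J per kcal divided by 86400 s per day.
#'
#' @param digits significant digits to round to; the model equations use the
#'   4-significant-figure value 0.04843. `NULL` returns the exact ratio.
#' @return conversion factor in W per (kcal/day).
#' @export
kcal_day_to_watts <- function(digits = 4) {
  x <- 4184 / 86400
  if (is.null(digits)) x else signif(x, digits)
}

#' Body mass index
#'
#' @param BM body mass, kg (> 0).
#' @param H height, cm (> 0).
#' @return BMI in kg/m^2: `BM / (H/100)^2`.
#' @export
bmi <- function(BM, H) {
  stopifnot(all(BM > 0), all(H > 0))
  BM / (H / 100)^2
}

#' Body surface area
#'
#' Power-law allometry in height and mass:
#' `BSA = 0.024265 * H^0.3964 * BM^0.5378` (H in cm, BM in kg).
#'
#' @inheritParams bmi
#' @return BSA in m^2.
#' @export
bsa <- function(H, BM) {
  stopifnot(all(H > 0), all(BM > 0))
  0.024265 * H^0.3964 * BM^0.5378
}

#' Basal metabolic rate
#'
#' Sex-specific linear equations in body mass, with the kcal/day result
#' converted to watts by the factor 0.04843:
#' female `0.04843 * (13.1 BM + 558)`, male `0.04843 * (16 BM + 545)`.
#'
#' @param sex `"female"` or `"male"`.
#' @param BM body mass, kg (> 0).
#' @return BMR in watts.
#' @export
bmr <- function(sex, BM) {
  stopifnot(all(BM > 0))
  sex <- match.arg(sex, c("female", "male"))
  k <- kcal_day_to_watts()
  if (sex == "female") k * (13.1 * BM + 558) else k * (16 * BM + 545)
}

#' Linear BMI-to-SCF relation
#'
#' @param sex `"female"` or `"male"`.
#' @param slope mm of SCF per unit BMI.
#' @param intercept mm.
#' @param variant `"standard"` (used for B2) or `"robustness"` (the flattened
#'   female / steepened male variant used for B3).
#' @return an object of class `scf_bmi_relation`.
#' @export
scf_bmi_relation <- function(sex, slope, intercept,
                             variant = c("standard", "robustness")) {
  sex <- match.arg(sex, c("female", "male"))
  variant <- match.arg(variant)
  rel <- structure(list(sex = sex, slope = slope, intercept = intercept,
                        variant = variant), class = "scf_bmi_relation")
  pred <- vapply(c(18, 35), function(b) slope * b + intercept, numeric(1))
  if (any(pred <= 0)) {
    stop("relation predicts nonpositive SCF over BMI in [18, 35]",
         call. = FALSE)
  }
  rel
}

#' Predict subcutaneous-fat thickness from BMI
#'
#' @param rel an [scf_bmi_relation()].
#' @param bmi BMI, kg/m^2 (within the calibrated range 18--35).
#' @return SCF in metres (`(slope * bmi + intercept)` mm, converted to m).
#' @export
scf_from_bmi <- function(rel, bmi) {
  stopifnot(inherits(rel, "scf_bmi_relation"))
  scf_mm <- rel$slope * bmi + rel$intercept
  if (any(scf_mm <= 0)) {
    stop("model-range error: predicted SCF is nonpositive", call. = FALSE)
  }
  scf_mm / 1000
}

#' Default BMI-SCF relations
#'
#' Four documented stand-in relations (sex x standard/robustness) obeying
#' the orderings the analysis depends on: the standard female slope exceeds
#' the standard male slope (female SCF more sensitive to BMI); the
#' robustness variant flattens the female slope below the standard female
#' one and steepens the male slope above the standard male one.
#'
#' @return named list with entries `female_standard`, `male_standard`,
#'   `female_robustness`, `male_robustness`.
#' @export
default_scf_relations <- function() {
  list(
    female_standard = scf_bmi_relation("female", 0.70, -10.0, "standard"),
    male_standard = scf_bmi_relation("male", 0.40, -4.0, "standard"),
    female_robustness = scf_bmi_relation("female", 0.35, -1.0, "robustness"),
    male_robustness = scf_bmi_relation("male", 0.55, -7.0, "robustness"))
}

#' Construct a body type
#'
#' @param sex `"female"` or `"male"`.
#' @param H height, cm.
#' @param BM body mass, kg.
#' @param SCF subcutaneous-fat thickness, m (> 0).
#' @param label body-type label, e.g. `"B1"`.
#' @return an object of class `body_type` with fields `sex`, `H`, `BM`,
#'   `BMI`, `SCF`, `label`.
#' @export
body_type <- function(sex, H, BM, SCF, label = "B1") {
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(H > 0, BM > 0, SCF > 0)
  structure(list(sex = sex, H = H, BM = BM, BMI = bmi(BM, H), SCF = SCF,
                 label = label), class = "body_type")
}

#' @export
print.body_type <- function(x, ...) {
  cat(sprintf("<body_type %s %s> H=%.1f cm BM=%.1f kg BMI=%.2f SCF=%.1f mm\n",
              x$label, x$sex, x$H, x$BM, x$BMI, x$SCF * 1000))
  invisible(x)
}

#' Derive a heavier body type at fixed height
#'
#' Same height and sex as the base; body mass is raised to produce exactly
#' the requested BMI increment, and SCF is re-predicted from the supplied
#' BMI-SCF relation at the new BMI.
#'
#' @param base a [body_type()].
#' @param bmi_increment BMI gain in kg/m^2 (2 in the standard design).
#' @param rel the [scf_bmi_relation()] used to set the derived SCF.
#' @param label label for the derived body.
#' @return a `body_type`.
#' @export
derive_body <- function(base, bmi_increment, rel, label) {
  stopifnot(inherits(base, "body_type"))
  new_bmi <- base$BMI + bmi_increment
  new_bm <- new_bmi * (base$H / 100)^2
  body_type(base$sex, base$H, new_bm, scf_from_bmi(rel, new_bmi), label)
}

#' Default six-body design
#'
#' B1 female/male from the configured baseline anthropometry (stand-in
#' defaults: female 166 cm / 70 kg, male 175 cm / 80 kg); B2 and B3 derived
#' by a two-unit BMI gain at fixed height with SCF from the standard and
#' robustness BMI-SCF relations respectively.
#'
#' @param base_female,base_male baseline [body_type()]s; defaults use an SCF
#'   of 0.005 m (the lower end of the 0.005--0.0075 m design range).
#' @param relations list as returned by [default_scf_relations()].
#' @param bmi_increment BMI gain for B2/B3, kg/m^2.
#' @return named list of six `body_type`s
#'   (`B1_female`, ..., `B3_male`).
#' @export
default_bodies <- function(base_female = body_type("female", 166, 70, 0.005, "B1"),
                           base_male = body_type("male", 175, 80, 0.005, "B1"),
                           relations = default_scf_relations(),
                           bmi_increment = 2) {
  list(
    B1_female = base_female,
    B1_male = base_male,
    B2_female = derive_body(base_female, bmi_increment,
                            relations$female_standard, "B2"),
    B2_male = derive_body(base_male, bmi_increment,
                          relations$male_standard, "B2"),
    B3_female = derive_body(base_female, bmi_increment,
                            relations$female_robustness, "B3"),
    B3_male = derive_body(base_male, bmi_increment,
                          relations$male_robustness, "B3"))
}

#' Tabulate body types as a data.frame
#'
#' @param bodies named list of [body_type()]s.
#' @return data.frame with one row per body.
#' @export
bodies_table <- function(bodies) {
  do.call(rbind, lapply(names(bodies), function(nm) {
    b <- bodies[[nm]]
    data.frame(name = nm, label = b$label, sex = b$sex, H_cm = b$H,
               BM_kg = b$BM, BMI = b$BMI, SCF_mm = b$SCF * 1000)
  }))
}
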