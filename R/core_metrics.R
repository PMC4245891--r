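#' Schofield resting metabolic rate coefficient tables
#'
#' Adult weight-only equations of the form RMR = slope * weight + intercept
#' (kcal/day), by sex and age band (18-30, 30-60, over 60). Two published
#' variants are bundled:
#'
#' * `"fao_kcal"` (default): the rounded kcal/day coefficients popularised by
#'   the FAO/WHO/UNU 1985 report (e.g. men 30-60: 11.6 W + 879).
#' * `"schofield_mj"`: Schofield's original MJ/day coefficients converted at
#'   239.006 kcal/MJ (e.g. men 30-60: 0.048 W + 3.653 MJ).
#'
#' @param variant Coefficient set to use.
#' @return A data frame with columns `sex`, `band`, `slope`, `intercept`
#'   (slope in kcal/day per kg, intercept in kcal/day).
#' @export
schofield_coefficients <- function(variant = c("fao_kcal", "schofield_mj")) {
  variant <- match.arg(variant)
  base <- data.frame(
    sex = rep(c("male", "female"), each = 3L),
    band = rep(c("18-30", "30-60", "60+"), 2L),
    stringsAsFactors = FALSE
  )
  if (variant == "fao_kcal") {
    base$slope <- c(15.3, 11.6, 13.5, 14.7, 8.7, 10.5)
    base$intercept <- c(679, 879, 487, 496, 829, 596)
  } else {
    kcal_per_mj <- 239.006
    base$slope <- c(0.063, 0.048, 0.049, 0.062, 0.034, 0.038) * kcal_per_mj
    base$intercept <- c(2.896, 3.653, 2.459, 2.036, 3.538, 2.755) * kcal_per_mj
  }
  base
}

#' Predicted resting metabolic rate (Schofield adult equations)
#'
#' Computes RMR (kcal/day) from sex, age and weight using the adult
#' weight-only Schofield equations. Age bands are 18-30, 30-60 and over 60;
#' by convention ages 30 and 60 both fall in the middle band (half-open lower
#' edge, closed upper edge), and ages above the last band (e.g. up to 79 in
#' survey data) use the over-60 equations.
#'
#' @param sex Sex, as 1/2, "M"/"F" or "male"/"female"; recycled against age
#'   and weight.
#' @param age_years Age in years; must be at least 18.
#' @param weight_kg Body weight in kg; must be positive.
#' @param variant Coefficient set, see [schofield_coefficients()].
#' @param band_edges Two ages splitting the adult bands; defaults to
#'   `c(30, 60)`. Band membership is `age < edge1`, `edge1 <= age <= edge2`,
#'   `age > edge2`.
#' @return Numeric vector of RMR in kcal/day.
#' @examples
#' schofield_rmr("male", 40, 70)    # 11.6 * 70 + 879 = 1691
#' schofield_rmr("female", 25, 60)  # 14.7 * 60 + 496 = 1378
#' @export
schofield_rmr <- function(sex, age_years, weight_kg,
                          variant = c("fao_kcal", "schofield_mj"),
                          band_edges = c(30, 60)) {
  variant <- match.arg(variant)
  sex <- canonical_sex(sex)
  n <- max(length(sex), length(age_years), length(weight_kg))
  sex <- rep_len(sex, n)
  age_years <- rep_len(age_years, n)
  weight_kg <- rep_len(weight_kg, n)
  if (any(!is.finite(age_years)) || any(!is.finite(weight_kg))) {
    stopf("age_years and weight_kg must be finite")
  }
  if (any(age_years < 18)) {
    stopf("schofield_rmr is defined for adults only (age_years >= 18)")
  }
  if (any(weight_kg <= 0)) stopf("weight_kg must be positive")
  if (length(band_edges) != 2L || band_edges[1] >= band_edges[2]) {
    stopf("band_edges must be two increasing ages")
  }
  tab <- schofield_coefficients(variant)
  band <- ifelse(age_years < band_edges[1], "18-30",
                 ifelse(age_years <= band_edges[2], "30-60", "60+"))
  idx <- match(paste(sex, band), paste(tab$sex, tab$band))
  tab$slope[idx] * weight_kg + tab$intercept[idx]
}

#' Physiological plausibility bounds for the energy-intake index
#'
#' Bounds on IndEI = EI/RMR (equivalently PAL = EE/RMR under energy
#' homeostasis). The defaults are a lower bound of 1 (expenditure cannot fall
#' below resting metabolism) and sex-specific upper bounds of 2.8 for women
#' and 3.5 for men, corresponding to extremely active individuals short of
#' endurance-athletic feats. The stricter Goldberg lower cut-off of 1.35 can
#' be requested via `min_indei = 1.35` but is not the default.
#'
#' @param min_indei Lower bound, applied to both sexes.
#' @param max_indei_female,max_indei_male Sex-specific upper bounds.
#' @return An object of class `plausibility_bounds`.
#' @export
plausibility_bounds <- function(min_indei = 1.0, max_indei_female = 2.8,
                                max_indei_male = 3.5) {
  if (!(min_indei > 0 && min_indei < max_indei_female &&
        max_indei_female <= max_indei_male)) {
    stopf("bounds must satisfy 0 < min < max_female <= max_male")
  }
  structure(list(min_indei = min_indei,
                 max_indei_female = max_indei_female,
                 max_indei_male = max_indei_male),
            class = "plausibility_bounds")
}

#' @export
print.plausibility_bounds <- function(x, ...) {
  cat(sprintf("IndEI plausibility bounds: [%.2f, %.2f] women, [%.2f, %.2f] men\n",
              x$min_indei, x$max_indei_female, x$min_indei, x$max_indei_male))
  invisible(x)
}

#' Percent energy misreporting
#'
#' Under energy homeostasis (intake = expenditure), percent misreporting is
#' `100 * (EE - EI_claimed) / EE`: positive values are under-reporting,
#' negative values over-reporting.
#'
#' @param ee_kcal Measured total energy expenditure, kcal/day; must be
#'   positive.
#' @param ei_claimed_kcal Self-reported energy intake, kcal/day; must be
#'   non-negative.
#' @return Percent misreporting on the 0-100 scale (can exceed the range for
#'   extreme over-reporting).
#' @examples
#' pct_misreport(2627, 2346)  # 10.70: mean under-reporting in a DLW cohort
#' @export
pct_misreport <- function(ee_kcal, ei_claimed_kcal) {
  if (any(!is.finite(ee_kcal)) || any(ee_kcal <= 0)) {
    stopf("ee_kcal must be finite and positive")
  }
  if (any(!is.finite(ei_claimed_kcal)) || any(ei_claimed_kcal < 0)) {
    stopf("ei_claimed_kcal must be finite and non-negative")
  }
  100 * (ee_kcal - ei_claimed_kcal) / ee_kcal
}

#' Classify the energy-intake index against plausibility bounds
#'
#' @param ind_ei EI/RMR values (unitless), finite and non-negative.
#' @param sex Sex vector, recycled.
#' @param bounds A [plausibility_bounds()] object.
#' @return Character vector with values `"implausible_low"`, `"plausible"`,
#'   `"implausible_high"`. Values exactly on a bound are plausible.
#' @export
classify_plausibility <- function(ind_ei, sex, bounds = plausibility_bounds()) {
  stopifnot(inherits(bounds, "plausibility_bounds"))
  if (any(!is.finite(ind_ei)) || any(ind_ei < 0)) {
    stopf("ind_ei must be finite and non-negative")
  }
  sex <- rep_len(canonical_sex(sex), length(ind_ei))
  upper <- ifelse(sex == "female", bounds$max_indei_female, bounds$max_indei_male)
  out <- rep("plausible", length(ind_ei))
  out[ind_ei < bounds$min_indei] <- "implausible_low"
  out[ind_ei > upper] <- "implausible_high"
  out
}

#' Weight status from BMI
#'
#' CDC/WHO categories: BMI < 18.5 underweight, > 25 overweight, > 30 obese,
#' otherwise normal (so overweight is (25, 30] and obese strictly above 30).
#'
#' @param weight_kg Weight in kg, positive.
#' @param height_cm Height in cm, positive.
#' @return Character vector in
#'   `c("underweight", "normal", "overweight", "obese")`.
#' @export
weight_status <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0) ||
      any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stopf("weight_kg and height_cm must be finite and positive")
  }
  bmi <- weight_kg / (height_cm / 100)^2
  out <- rep("normal", length(bmi))
  out[bmi < 18.5] <- "underweight"
  out[bmi > 25] <- "overweight"
  out[bmi > 30] <- "obese"
  out
}

#' Derive energy-balance quantities for a person table
#'
#' Adds RMR (Schofield), the claimed energy-intake index
#' `ind_ei_claimed = ei_claimed_kcal / rmr_kcal`, and, where measured
#' expenditure `ee_kcal` is available (validation-study data), the physical
#' activity level `pal = ee_kcal / rmr_kcal` and percent misreporting.
#' A plausibility label for the claimed index is included.
#'
#' @param persons Data frame with columns `sex`, `age_years`, `weight_kg`,
#'   `ei_claimed_kcal` and optionally `ee_kcal`.
#' @param bounds A [plausibility_bounds()] object.
#' @param variant Schofield coefficient variant.
#' @return `persons` with columns `rmr_kcal`, `ind_ei_claimed`, `pal`,
#'   `pct_misreport` (NA where `ee_kcal` is absent) and `plausibility`.
#' @export
derive_profile <- function(persons, bounds = plausibility_bounds(),
                           variant = "fao_kcal") {
  require_columns(persons, c("sex", "age_years", "weight_kg", "ei_claimed_kcal"),
                  "person table")
  if (any(!is.finite(persons$ei_claimed_kcal)) ||
      any(persons$ei_claimed_kcal < 0)) {
    stopf("ei_claimed_kcal must be finite and non-negative")
  }
  persons$rmr_kcal <- schofield_rmr(persons$sex, persons$age_years,
                                    persons$weight_kg, variant = variant)
  persons$ind_ei_claimed <- persons$ei_claimed_kcal / persons$rmr_kcal
  if ("ee_kcal" %in% names(persons) && any(!is.na(persons$ee_kcal))) {
    has_ee <- !is.na(persons$ee_kcal)
    persons$pal <- NA_real_
    persons$pal[has_ee] <- persons$ee_kcal[has_ee] / persons$rmr_kcal[has_ee]
    persons$pct_misreport <- NA_real_
    persons$pct_misreport[has_ee] <- pct_misreport(
      persons$ee_kcal[has_ee], persons$ei_claimed_kcal[has_ee])
  } else {
    persons$pal <- NA_real_
    persons$pct_misreport <- NA_real_
  }
  persons$plausibility <- classify_plausibility(persons$ind_ei_claimed,
                                                persons$sex, bounds)
  persons
}
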