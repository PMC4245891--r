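# Synthetic cohorts. Two training-style generators (a regression-faithful
# cohort with a known misreporting model, and a PAL-first cohort with a known
# constant caloric offset) plus a survey-style test population. All are
# deterministic given `seed` and never touch the caller's RNG state.

draw_sex <- function(n, fraction_female) {
  ifelse(stats::runif(n) < fraction_female, "female", "male")
}

default_heights <- function(sex) {
  # Per-sex adult height moments (cm), typical of US survey populations.
  m <- ifelse(sex == "male", 175.6, 162.2)
  s <- ifelse(sex == "male", 7.4, 6.9)
  stats::rnorm(length(sex), m, s)
}

#' Generate a validation-cohort-like training table with known misreporting
#'
#' Emulates a doubly-labeled-water validation cohort (ages 40-69) in which
#' percent misreporting follows a known linear model, so that refitting can
#' be checked against ground truth. Per person: sex, age (uniform integer in
#' `age_range`), weight (truncated normal above 35 kg, moment-matched to the
#' target mean/SD) and claimed intake (log-normal matched to the target
#' moments) are drawn independently; percent misreporting is the model's
#' linear predictor at the drawn covariates plus Gaussian noise (capped
#' below 99); measured expenditure is then `EE = EI_claimed / (1 - pct/100)`,
#' which makes the observed misreporting of every generated record exactly
#' `linear predictor + noise`. Drawing intake exogenously (rather than
#' deriving it from an activity level) is what guarantees exact coefficient
#' recovery: the model's covariates include functions of claimed intake, so
#' intake cannot itself be derived from the model without a circular
#' definition. The physical activity level `EE/RMR` is consequently a derived
#' quantity here; use [generate_offset_population()] for cohorts with a
#' controlled PAL distribution.
#'
#' @param n Number of persons.
#' @param sex_fraction_female Probability of female, default 0.457.
#' @param age_range Inclusive integer age range, default 40-69.
#' @param weight_mean,weight_sd Weight moments in kg, default 81.0 / 17.6.
#' @param ei_mean,ei_sd Claimed-intake moments in kcal, default 2346 / 808.
#' @param model Ground-truth [misreport_model()]; default the bundled
#'   published coefficients.
#' @param noise_sd SD of the additive Gaussian noise on percent
#'   misreporting, default 5.
#' @param seed Optional integer seed.
#' @param variant Schofield variant used for the IndEI covariate.
#' @return Person table with `ee_kcal` (training data) and `pct_true`.
#' @export
generate_open_like <- function(n, sex_fraction_female = 0.457,
                               age_range = c(40, 69),
                               weight_mean = 81.0, weight_sd = 17.6,
                               ei_mean = 2346, ei_sd = 808,
                               model = default_open_model(),
                               noise_sd = 5, seed = NULL,
                               variant = "fao_kcal") {
  if (!is_count(n)) stopf("n must be a positive integer")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (sex_fraction_female < 0 || sex_fraction_female > 1) {
    stopf("sex_fraction_female must be a probability")
  }
  if (age_range[1] < 18) stopf("age_range must start at 18 or above")
  stopifnot(inherits(model, "misreport_model"))
  with_seed(seed, {
    sex <- draw_sex(n, sex_fraction_female)
    age <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
    weight <- rnorm_trunc_matched(n, weight_mean, weight_sd, lower = 35)
    height <- default_heights(sex)
    lp <- lognormal_params_from_moments(ei_mean, ei_sd)
    ei <- stats::rlnorm(n, lp[["meanlog"]], lp[["sdlog"]])
    rmr <- schofield_rmr(sex, age, weight, variant = variant)
    persons <- data.frame(id = sprintf("open%06d", seq_len(n)), sex = sex,
                          age_years = age, weight_kg = weight,
                          height_cm = height, ei_claimed_kcal = ei,
                          stringsAsFactors = FALSE)
    pct <- predict_pct_misreport(model, persons, rmr_kcal = rmr) +
      stats::rnorm(n, 0, noise_sd)
    pct <- pmin(pct, 99)  # keeps derived expenditure finite and positive
    persons$ee_kcal <- ei / (1 - pct / 100)
    persons$pct_true <- pct
    persons$special_diet <- FALSE
    persons$atypical_day <- FALSE
    persons$nonreporter <- FALSE
    persons$race_group <- "nonblack"
    persons
  })
}

#' Generate a PAL-first cohort with a known constant caloric under-report
#'
#' Emulates a cohort in which every individual's true intake equals
#' expenditure and reporting is biased by a fixed per-sex number of
#' calories: PAL is drawn from a per-sex log-normal (truncated to the
#' physiologic range (1.05, 4.5), negligible mass at the default
#' parameters), `EE = PAL * RMR`, and `EI_claimed = max(EE - offset, 0)`.
#' The rank-alignment shift estimator should recover the injected offsets.
#'
#' @param n Number of persons.
#' @param offset_male,offset_female Injected under-report in kcal/day.
#' @param sex_fraction_female,age_range,weight_mean,weight_sd As in
#'   [generate_open_like()].
#' @param pal Named list of per-sex [pal_distribution()]s; defaults to the
#'   reference cohort distributions.
#' @param pal_range Truncation interval for PAL draws.
#' @param seed Optional integer seed.
#' @param variant Schofield variant.
#' @return Person table with `ee_kcal` and `pal_true`.
#' @export
generate_offset_population <- function(n, offset_male = 905,
                                       offset_female = 600,
                                       sex_fraction_female = 0.457,
                                       age_range = c(40, 69),
                                       weight_mean = 81.0, weight_sd = 17.6,
                                       pal = list(male = default_open_pal("male"),
                                                  female = default_open_pal("female")),
                                       pal_range = c(1.05, 4.5),
                                       seed = NULL, variant = "fao_kcal") {
  if (!is_count(n)) stopf("n must be a positive integer")
  with_seed(seed, {
    sex <- draw_sex(n, sex_fraction_female)
    age <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
    weight <- rnorm_trunc_matched(n, weight_mean, weight_sd, lower = 35)
    height <- default_heights(sex)
    rmr <- schofield_rmr(sex, age, weight, variant = variant)
    pal_v <- numeric(n)
    for (s in c("male", "female")) {
      rows <- which(sex == s)
      if (!length(rows)) next
      d <- pal[[s]]
      p_lo <- stats::plnorm(pal_range[1], d$log_mean, d$log_sd)
      p_hi <- stats::plnorm(pal_range[2], d$log_mean, d$log_sd)
      pal_v[rows] <- stats::qlnorm(stats::runif(length(rows), p_lo, p_hi),
                                   d$log_mean, d$log_sd)
    }
    ee <- pal_v * rmr
    offset <- ifelse(sex == "male", offset_male, offset_female)
    data.frame(id = sprintf("off%06d", seq_len(n)), sex = sex,
               age_years = age, weight_kg = weight, height_cm = height,
               ei_claimed_kcal = pmax(ee - offset, 0), ee_kcal = ee,
               pal_true = pal_v, race_group = "nonblack",
               stringsAsFactors = FALSE)
  })
}

# Split pooled intake moments into per-sex moments: means in the given
# male/female ratio, SDs with a common coefficient of variation, chosen so
# the pooled mean and SD are preserved exactly.
per_sex_ei_moments <- function(pooled_mean, pooled_sd, p_female, ratio) {
  mean_f <- pooled_mean / (ratio + p_female * (1 - ratio))
  mean_m <- ratio * mean_f
  between <- p_female * (1 - p_female) * (mean_m - mean_f)^2
  if (between >= pooled_sd^2) {
    stopf("sex gap in mean intake exceeds the pooled variance")
  }
  cv2 <- (pooled_sd^2 - between) /
    ((1 - p_female) * mean_m^2 + p_female * mean_f^2)
  list(male = c(mean = mean_m, sd = sqrt(cv2) * mean_m),
       female = c(mean = mean_f, sd = sqrt(cv2) * mean_f))
}

flavor_moments <- function(flavor) {
  switch(flavor,
         "2007" = list(ei = c(mean = 2120, sd = 1050),
                       weight = c(mean = 80.0, sd = 20.7),
                       age_max = 79, p_black = 0.211),
         "1971" = list(ei = c(mean = 1876, sd = 884),
                       weight = c(mean = 69.2, sd = 15.3),
                       age_max = 74, p_black = 0.146),
         stopf("unknown flavor '%s' (use \"1971\" or \"2007\")", flavor))
}

# Per-sex multiplicative intake scale achieving a target implausible
# fraction, solved on the under-reporting (decreasing) branch of the
# failure-rate curve.
solve_intake_scale <- function(ei, rmr, sex_upper, target, min_indei = 1) {
  frac <- function(s) mean(s * ei / rmr < min_indei | s * ei / rmr > sex_upper)
  grid <- seq(0.25, 4, by = 0.05)
  f <- vapply(grid, frac, numeric(1))
  i_min <- which.min(f)
  if (target < f[i_min]) {
    stopf("implausible_fraction_target %.3f below the achievable minimum %.3f",
          target, f[i_min])
  }
  lo <- grid[1]
  if (frac(lo) < target) stopf("target fraction not reachable by down-scaling")
  stats::uniroot(function(s) frac(s) - target, c(lo, grid[i_min]),
                 tol = 1e-6)$root
}

#' Generate a survey-like test population with age-sex strata
#'
#' Emulates a national-survey person file after exclusions: within each
#' sex, weight and claimed intake are truncated normals whose parents are
#' moment-matched so the generated sample hits the flavor's target mean/SD
#' (claimed intake 2120/1050 kcal for the 2007-like flavor, 1876/884 for the
#' 1971-like flavor; weights 80.0/20.7 and 69.2/15.3 kg). When
#' `implausible_fraction_target` is given, claimed intake is rescaled by a
#' per-sex multiplicative factor (solved on the under-reporting branch) so
#' that the requested fraction of the generated population falls outside the
#' plausibility bounds; the intake moments then no longer apply.
#'
#' Two features of real survey intake are emulated because without them the
#' spread of the intake index EI/RMR is unrealistically wide: men report
#' systematically more calories than women (`sex_ei_ratio`, default 1.40;
#' the pooled flavor moments are preserved exactly by construction), and
#' within each sex reported intake correlates with body size
#' (`ei_rmr_correlation`, default 0.45, induced by rank reordering that
#' leaves the per-sex intake marginal untouched).
#'
#' @param sex_ei_ratio Male/female ratio of mean reported intake.
#' @param n Number of persons.
#' @param flavor `"2007"` or `"1971"`.
#' @param sex_fraction_female Probability of female, default 0.51.
#' @param implausible_fraction_target Optional target for the out-of-bounds
#'   fraction of the claimed energy-intake index.
#' @param ei_rmr_correlation Rank correlation between claimed intake and
#'   predicted RMR; 0 draws intake independently.
#' @param age_bin_edges Bin edges for the returned stratum table.
#' @param bounds Plausibility bounds used when targeting a fraction.
#' @param seed Optional integer seed.
#' @param variant Schofield variant.
#' @return List with `persons` (person table), `strata` (a
#'   [build_strata()] result) and `intake_scale` (named per-sex scale
#'   factors; 1 when no target was requested).
#' @export
generate_nhanes_like <- function(n, flavor = c("2007", "1971"),
                                 sex_fraction_female = 0.51,
                                 implausible_fraction_target = NULL,
                                 sex_ei_ratio = 1.40,
                                 ei_rmr_correlation = 0.45,
                                 age_bin_edges = c(18, 30, 40, 50, 60, 70),
                                 bounds = plausibility_bounds(),
                                 seed = NULL, variant = "fao_kcal") {
  if (!is_count(n)) stopf("n must be a positive integer")
  if (is.character(flavor)) flavor <- flavor[1]
  mom <- flavor_moments(as.character(flavor))
  if (!is.null(implausible_fraction_target) &&
      (implausible_fraction_target <= 0 || implausible_fraction_target >= 1)) {
    stopf("implausible_fraction_target must be in (0, 1)")
  }
  with_seed(seed, {
    sex <- draw_sex(n, sex_fraction_female)
    age <- sample(seq(18, mom$age_max), n, replace = TRUE)
    weight <- rnorm_trunc_matched(n, mom$weight[["mean"]], mom$weight[["sd"]],
                                  lower = 35)
    height <- default_heights(sex)
    rmr <- schofield_rmr(sex, age, weight, variant = variant)
    ei_mom <- per_sex_ei_moments(mom$ei[["mean"]], mom$ei[["sd"]],
                                 mean(sex == "female"), sex_ei_ratio)
    ei <- numeric(n)
    for (s in c("male", "female")) {
      rows <- which(sex == s)
      if (!length(rows)) next
      e <- rnorm_trunc_matched(length(rows), ei_mom[[s]][["mean"]],
                               ei_mom[[s]][["sd"]], lower = 300)
      if (ei_rmr_correlation != 0 && length(rows) > 1) {
        # Iman-Conover style coupling within sex: reassign the intake draws
        # to the ranks of a score correlated with RMR, preserving the
        # per-sex intake marginal.
        r <- ei_rmr_correlation
        z <- (rmr[rows] - mean(rmr[rows])) / stats::sd(rmr[rows])
        score <- r * z + sqrt(1 - r^2) * stats::rnorm(length(rows))
        e <- sort(e)[rank(score, ties.method = "first")]
      }
      ei[rows] <- e
    }
    race <- ifelse(stats::runif(n) < mom$p_black, "black", "nonblack")
    scale <- c(male = 1, female = 1)
    if (!is.null(implausible_fraction_target)) {
      for (s in c("male", "female")) {
        rows <- which(sex == s)
        if (!length(rows)) next
        upper <- if (s == "female") bounds$max_indei_female else bounds$max_indei_male
        scale[[s]] <- solve_intake_scale(ei[rows], rmr[rows], upper,
                                         implausible_fraction_target,
                                         bounds$min_indei)
        ei[rows] <- ei[rows] * scale[[s]]
      }
    }
    persons <- data.frame(id = sprintf("nh%06d", seq_len(n)), sex = sex,
                          age_years = age, weight_kg = weight,
                          height_cm = height, ei_claimed_kcal = ei,
                          special_diet = FALSE, atypical_day = FALSE,
                          nonreporter = FALSE, race_group = race,
                          stringsAsFactors = FALSE)
    list(persons = persons,
         strata = build_strata(persons, age_bin_edges),
         intake_scale = scale)
  })
}

#' Bundled synthetic census age-sex weights
#'
#' A self-contained stand-in for a census age-sex distribution: uniform
#' probability across age bins within sex, with a 0.49/0.51 male/female
#' split. Reproducing published survey results requires supplying real
#' census weights in the same format.
#'
#' @param flavor `"1971"` or `"2007"` (validated; the synthetic default is
#'   the same for both).
#' @param age_bin_edges Age bin edges matching the stratum table.
#' @return Data frame with columns `sex`, `age_bin`, `weight` summing to 1.
#' @export
default_agesex_weights <- function(flavor = c("2007", "1971"),
                                   age_bin_edges = c(18, 30, 40, 50, 60, 70)) {
  flavor <- as.character(flavor[1])
  if (!flavor %in% c("1971", "2007")) {
    stopf("unknown flavor '%s' (use \"1971\" or \"2007\")", flavor)
  }
  labs <- age_bin_labels(age_bin_edges)
  out <- expand.grid(sex = c("male", "female"), age_bin = labs,
                     stringsAsFactors = FALSE)
  out$weight <- ifelse(out$sex == "male", 0.49, 0.51) / length(labs)
  out
}
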