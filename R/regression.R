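#' Linear model of percent energy misreporting
#'
#' Container for a linear predictor of percent misreporting (0-100 scale,
#' positive = under-reporting) in five covariates: sex code (1 = male,
#' 2 = female), age in years, weight in kg, log claimed intake, and the
#' claimed energy-intake index IndEI = EI/RMR.
#'
#' @param intercept,beta_sex,beta_age,beta_weight,beta_log_ei,beta_ind_ei
#'   Model coefficients (percent per unit of each covariate). All must be
#'   finite; a coefficient of 0 drops the covariate from the predictor.
#' @param log_convention Base of the log applied to claimed intake:
#'   `"natural"` or `"base10"`. Stored with the model so that corrections are
#'   reproducible.
#' @param r_squared Optional coefficient of determination in \[0, 1\].
#' @param source `"paper_table2"` for the bundled published coefficients or
#'   `"refit"` for models estimated from data.
#' @param coef_table Optional coefficient summary matrix (estimate, SE, t, p)
#'   retained from a fit.
#' @return An object of class `misreport_model`.
#' @seealso [default_open_model()], [fit_misreport_model()]
#' @export
misreport_model <- function(intercept, beta_sex, beta_age, beta_weight,
                            beta_log_ei, beta_ind_ei,
                            log_convention = c("natural", "base10"),
                            r_squared = NULL,
                            source = c("refit", "paper_table2"),
                            coef_table = NULL) {
  log_convention <- match.arg(log_convention)
  source <- match.arg(source)
  coefs <- c(intercept = intercept, beta_sex = beta_sex, beta_age = beta_age,
             beta_weight = beta_weight, beta_log_ei = beta_log_ei,
             beta_ind_ei = beta_ind_ei)
  if (any(!is.finite(coefs))) stopf("all model coefficients must be finite")
  if (!is.null(r_squared) &&
      (!is.finite(r_squared) || r_squared < 0 || r_squared > 1)) {
    stopf("r_squared must lie in [0, 1]")
  }
  structure(list(intercept = intercept, beta_sex = beta_sex,
                 beta_age = beta_age, beta_weight = beta_weight,
                 beta_log_ei = beta_log_ei, beta_ind_ei = beta_ind_ei,
                 log_convention = log_convention, r_squared = r_squared,
                 source = source, coef_table = coef_table),
            class = "misreport_model")
}

#' @export
print.misreport_model <- function(x, ...) {
  cat("Percent-misreporting model (", x$source, ", ",
      x$log_convention, " log)\n", sep = "")
  co <- c(intercept = x$intercept, sex = x$beta_sex, age = x$beta_age,
          weight = x$beta_weight, log_ei = x$beta_log_ei,
          ind_ei = x$beta_ind_ei)
  print(round(co, 4))
  if (!is.null(x$r_squared)) cat(sprintf("R-squared: %.3f\n", x$r_squared))
  invisible(x)
}

#' The bundled OPEN-study misreporting model
#'
#' Returns the published linear model of percent misreporting fitted to
#' non-Black participants of the OPEN doubly-labeled-water validation study:
#' intercept 298.19, sex -2.30, age -0.36 per year, weight 0.21 per kg,
#' log claimed intake -35.84, claimed intake index -30.47; R-squared 0.84.
#' The sex coefficient was not significant in the source fit but is retained
#' as printed. The base of the published log term is not stated; natural log
#' is the package default, selected by [calibrate_log_convention()] as the
#' convention whose population-mean prediction is closer to the observed
#' training-cohort mean misreporting.
#'
#' @param log_convention Log convention to attach, default natural.
#' @return A [misreport_model()] with `source = "paper_table2"`.
#' @export
default_open_model <- function(log_convention = c("natural", "base10")) {
  misreport_model(intercept = 298.19, beta_sex = -2.30, beta_age = -0.36,
                  beta_weight = 0.21, beta_log_ei = -35.84,
                  beta_ind_ei = -30.47,
                  log_convention = match.arg(log_convention),
                  r_squared = 0.84, source = "paper_table2")
}

model_log <- function(model) {
  if (model$log_convention == "natural") log else log10
}

#' Predict percent misreporting for individuals
#'
#' Evaluates the linear predictor of a [misreport_model()] for each person:
#' `intercept + b_sex*sexcode + b_age*age + b_weight*weight +
#' b_log_ei*log(EI) + b_ind_ei*(EI/RMR)`.
#'
#' @param model A [misreport_model()].
#' @param persons Data frame with `sex`, `age_years`, `weight_kg`,
#'   `ei_claimed_kcal` (all claimed intakes must be positive so the log is
#'   defined).
#' @param rmr_kcal Optional precomputed RMR vector; computed with
#'   [schofield_rmr()] when omitted.
#' @param variant Schofield variant used when `rmr_kcal` is omitted.
#' @return Numeric vector of predicted percent misreporting (uncapped).
#' @export
predict_pct_misreport <- function(model, persons, rmr_kcal = NULL,
                                  variant = "fao_kcal") {
  stopifnot(inherits(model, "misreport_model"))
  require_columns(persons, c("sex", "age_years", "weight_kg", "ei_claimed_kcal"),
                  "person table")
  ei <- persons$ei_claimed_kcal
  if (any(!is.finite(ei)) || any(ei <= 0)) {
    stopf("ei_claimed_kcal must be positive (log undefined at 0)")
  }
  if (is.null(rmr_kcal)) {
    rmr_kcal <- schofield_rmr(persons$sex, persons$age_years,
                              persons$weight_kg, variant = variant)
  }
  if (any(rmr_kcal <= 0)) stopf("rmr_kcal must be positive")
  lg <- model_log(model)
  model$intercept +
    model$beta_sex * sex_code(persons$sex) +
    model$beta_age * persons$age_years +
    model$beta_weight * persons$weight_kg +
    model$beta_log_ei * lg(ei) +
    model$beta_ind_ei * (ei / rmr_kcal)
}

#' Invert predicted misreporting into corrected intake
#'
#' Under the homeostasis assumption (true intake = expenditure), percent
#' misreporting p satisfies `EI_claimed = EI * (1 - p/100)`, so the corrected
#' intake is `EI_claimed / (1 - p/100)`. Predictions are first clamped to
#' `[-cap, cap]` so that covariate extremes cannot drive the denominator to
#' zero.
#'
#' @param ei_claimed_kcal Claimed intake, kcal/day, non-negative.
#' @param pct Percent misreporting (predicted or observed).
#' @param cap Symmetric clamp applied to `pct` before inversion; default 99.
#' @return Corrected intake in kcal/day.
#' @examples
#' correct_ei(1000, 50)        # 2000
#' correct_ei(2346, 10.70)     # ~2627
#' @export
correct_ei <- function(ei_claimed_kcal, pct, cap = 99) {
  if (any(!is.finite(ei_claimed_kcal)) || any(ei_claimed_kcal < 0)) {
    stopf("ei_claimed_kcal must be finite and non-negative")
  }
  if (!is.numeric(cap) || length(cap) != 1L || cap <= 0) {
    stopf("cap must be a single positive number")
  }
  pct <- pmin(pmax(pct, -cap), cap)
  if (any(pct >= 100)) {
    stopf("percent misreporting must stay below 100 after capping")
  }
  ei_claimed_kcal / (1 - pct / 100)
}

# Canonical covariate frame used by the fitting routines.
misreport_design <- function(training, log_convention, variant) {
  require_columns(training,
                  c("sex", "age_years", "weight_kg", "ei_claimed_kcal",
                    "ee_kcal"), "training table")
  if (any(!is.finite(training$ee_kcal)) || any(training$ee_kcal <= 0)) {
    stopf("training rows must have positive measured ee_kcal")
  }
  if (any(!is.finite(training$ei_claimed_kcal)) ||
      any(training$ei_claimed_kcal <= 0)) {
    stopf("training rows must have positive ei_claimed_kcal")
  }
  rmr <- schofield_rmr(training$sex, training$age_years, training$weight_kg,
                       variant = variant)
  lg <- if (log_convention == "natural") log else log10
  data.frame(
    pct = pct_misreport(training$ee_kcal, training$ei_claimed_kcal),
    sex_code = sex_code(training$sex),
    age_years = training$age_years,
    weight_kg = training$weight_kg,
    log_ei = lg(training$ei_claimed_kcal),
    ind_ei = training$ei_claimed_kcal / rmr
  )
}

#' Fit the misreporting regression to validation data
#'
#' Ordinary least squares of observed percent misreporting (from measured
#' expenditure and claimed intake) on the five standard covariates. Mirrors
#' the published modelling choice of excluding Black participants by default
#' (reporting behaviour differed and the training subgroup was too small to
#' model separately); set `exclude_black = FALSE` to fit to all rows.
#'
#' @param training Data frame with `sex`, `age_years`, `weight_kg`,
#'   `ei_claimed_kcal`, `ee_kcal` and optionally `race_group`.
#' @param log_convention Log applied to claimed intake.
#' @param variant Schofield variant for the IndEI covariate.
#' @param exclude_black Drop rows with `race_group == "black"` before
#'   fitting, when that column is present.
#' @param min_n Minimum rows required after exclusions (default 20).
#' @return A [misreport_model()] with `source = "refit"`, the fitted
#'   R-squared, and the coefficient summary in `$coef_table`.
#' @export
fit_misreport_model <- function(training,
                                log_convention = c("natural", "base10"),
                                variant = "fao_kcal", exclude_black = TRUE,
                                min_n = 20) {
  log_convention <- match.arg(log_convention)
  if (exclude_black && "race_group" %in% names(training)) {
    training <- training[training$race_group != "black" |
                           is.na(training$race_group), , drop = FALSE]
  }
  if (nrow(training) < min_n) {
    stopf("need at least %d training rows, got %d", min_n, nrow(training))
  }
  dat <- misreport_design(training, log_convention, variant)
  fit <- stats::lm(pct ~ sex_code + age_years + weight_kg + log_ei + ind_ei,
                   data = dat)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stopf("design is rank deficient; collinear term(s): %s",
          paste(names(co)[is.na(co)], collapse = ", "))
  }
  sm <- summary(fit)
  misreport_model(intercept = co[["(Intercept)"]],
                  beta_sex = co[["sex_code"]],
                  beta_age = co[["age_years"]],
                  beta_weight = co[["weight_kg"]],
                  beta_log_ei = co[["log_ei"]],
                  beta_ind_ei = co[["ind_ei"]],
                  log_convention = log_convention,
                  r_squared = sm$r.squared, source = "refit",
                  coef_table = sm$coefficients)
}

#' Backward stepwise elimination for the misreporting regression
#'
#' Starting from a candidate covariate set, repeatedly refits the OLS model
#' and removes the single covariate with the largest two-sided t-test
#' p-value above `alpha`, until every remaining covariate is significant.
#' The intercept is never removed. Ties in p-value are broken by removing
#' the covariate listed later in `candidates`.
#'
#' @param training Training table as for [fit_misreport_model()].
#' @param candidates Covariate names. The five canonical names
#'   (`sex_code`, `age_years`, `weight_kg`, `log_ei`, `ind_ei`) are
#'   constructed from the training table; any other name must be a numeric
#'   column of `training` and enters the model as-is.
#' @param alpha Retention threshold on the two-sided p-value, default 0.05.
#' @param log_convention,variant,exclude_black As in
#'   [fit_misreport_model()].
#' @return An object of class `stepwise_fit`: list with `retained` (covariate
#'   names), `coefficients`, `p_values`, `trace` (one row per elimination),
#'   `fit` (the final `lm`), and `model` (a [misreport_model()] with zeros
#'   for eliminated canonical covariates, or NULL when non-canonical
#'   covariates survive).
#' @export
backward_eliminate <- function(training,
                               candidates = c("sex_code", "age_years",
                                              "weight_kg", "log_ei",
                                              "ind_ei"),
                               alpha = 0.05,
                               log_convention = c("natural", "base10"),
                               variant = "fao_kcal", exclude_black = TRUE) {
  log_convention <- match.arg(log_convention)
  if (!length(candidates)) stopf("candidates must be non-empty")
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stopf("alpha must be a single probability in (0, 1)")
  }
  if (exclude_black && "race_group" %in% names(training)) {
    training <- training[training$race_group != "black" |
                           is.na(training$race_group), , drop = FALSE]
  }
  dat <- misreport_design(training, log_convention, variant)
  canonical <- c("sex_code", "age_years", "weight_kg", "log_ei", "ind_ei")
  extra <- setdiff(candidates, canonical)
  for (nm in extra) {
    if (!nm %in% names(training) || !is.numeric(training[[nm]])) {
      stopf("candidate '%s' is not a numeric column of the training table", nm)
    }
    dat[[nm]] <- training[[nm]]
  }

  current <- candidates
  trace <- data.frame(step = integer(), dropped = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fml <- stats::reformulate(current, response = "pct")
    fit <- stats::lm(fml, data = dat)
    co <- stats::coef(fit)
    if (anyNA(co)) {
      stopf("design is rank deficient; collinear term(s): %s",
            paste(names(co)[is.na(co)], collapse = ", "))
    }
    pv <- summary(fit)$coefficients[, "Pr(>|t|)"]
    pv <- pv[setdiff(names(pv), "(Intercept)")]
    if (!length(pv) || max(pv) <= alpha) break
    worst <- names(pv)[pv == max(pv)]
    drop_nm <- worst[which.max(match(worst, candidates))]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = drop_nm,
                                     p_value = pv[[drop_nm]],
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, drop_nm)
    if (!length(current)) {  # intercept-only model
      fit <- stats::lm(pct ~ 1, data = dat)
      break
    }
  }

  co <- stats::coef(fit)
  pv_all <- summary(fit)$coefficients[, "Pr(>|t|)"]
  model <- NULL
  if (all(current %in% canonical)) {
    get_b <- function(nm) if (nm %in% names(co)) co[[nm]] else 0
    model <- misreport_model(intercept = co[["(Intercept)"]],
                             beta_sex = get_b("sex_code"),
                             beta_age = get_b("age_years"),
                             beta_weight = get_b("weight_kg"),
                             beta_log_ei = get_b("log_ei"),
                             beta_ind_ei = get_b("ind_ei"),
                             log_convention = log_convention,
                             r_squared = summary(fit)$r.squared,
                             source = "refit",
                             coef_table = summary(fit)$coefficients)
  }
  structure(list(retained = current, coefficients = co, p_values = pv_all,
                 trace = trace, fit = fit, model = model),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Backward stepwise fit: retained",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  if (nrow(x$trace)) {
    cat("Eliminated in order:",
        paste(sprintf("%s (p=%.3f)", x$trace$dropped, x$trace$p_value),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Normal quantile-quantile diagnostic for percent misreporting
#'
#' Pairs the sorted observed values with standard-normal quantiles at the
#' plotting positions `ppoints(n)` and reports the least-squares line through
#' the pairs; for approximately normal data the slope estimates the sample SD
#' and the intercept the mean. Used to check that percent misreporting is
#' close enough to normal for a linear model.
#'
#' @param values Numeric vector, length at least 3.
#' @return Object of class `qq_diagnostic`: list with `theoretical`,
#'   `observed`, `slope`, `intercept`.
#' @export
normality_diagnostic <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stopf("need at least 3 finite values for a QQ diagnostic")
  theoretical <- stats::qnorm(stats::ppoints(n))
  observed <- sort(values)
  fit <- stats::lm(observed ~ theoretical)
  structure(list(theoretical = theoretical, observed = observed,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "qq_diagnostic")
}

#' @export
print.qq_diagnostic <- function(x, ...) {
  cat(sprintf("QQ diagnostic on %d values: line slope %.3f, intercept %.3f\n",
              length(x$observed), x$slope, x$intercept))
  invisible(x)
}

#' @export
plot.qq_diagnostic <- function(x, ...) {
  graphics::plot(x$theoretical, x$observed,
                 xlab = "Standard normal quantiles",
                 ylab = "Observed quantiles", ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}

#' Recentre a misreporting model's intercept to a target mean
#'
#' Shifts the intercept so that the model's population-mean predicted
#' misreporting on a reference population equals a target (for instance the
#' observed mean misreporting of a validation cohort). Slope coefficients
#' are untouched. This is useful when published coefficients, applied to a
#' population reconstructed from summary moments, predict a mean that is
#' inconsistent with the training cohort's observed mean — recentring
#' restores the calibration of the overall level while keeping the
#' published covariate effects. The result is marked `source = "refit"` to
#' make clear it is no longer the published model verbatim.
#'
#' @param model A [misreport_model()].
#' @param persons Reference population.
#' @param target_pct Desired population-mean predicted misreporting;
#'   defaults to the observed mean when `persons` carries `ee_kcal`.
#' @param variant Schofield variant for the IndEI covariate.
#' @return The recentred [misreport_model()].
#' @export
recenter_model <- function(model, persons, target_pct = NULL,
                           variant = "fao_kcal") {
  stopifnot(inherits(model, "misreport_model"))
  if (is.null(target_pct)) {
    if (!"ee_kcal" %in% names(persons) || all(is.na(persons$ee_kcal))) {
      stopf("persons has no ee_kcal; supply target_pct")
    }
    ok <- !is.na(persons$ee_kcal)
    target_pct <- mean(pct_misreport(persons$ee_kcal[ok],
                                     persons$ei_claimed_kcal[ok]))
  }
  current <- mean(predict_pct_misreport(model, persons, variant = variant))
  out <- model
  out$intercept <- model$intercept + (target_pct - current)
  out$source <- "refit"
  out$coef_table <- NULL
  out
}

#' Choose the log convention (and RMR variant) for the bundled model
#'
#' The base of the log term in the published misreporting model is not
#' recorded, and neither is the exact RMR equation variant. This routine
#' evaluates the bundled coefficients under both log conventions and both
#' Schofield variants on a reference population and reports, for each
#' combination, the population-mean predicted misreporting and its distance
#' to the observed mean (computed from measured `ee_kcal` when present,
#' otherwise supplied via `target_pct`). The closest combination is
#' recommended and returned as a ready-to-use model.
#'
#' @param persons Reference population (training-study-like); needs the four
#'   predictor columns and ideally `ee_kcal`.
#' @param target_pct Observed mean percent misreporting to match when
#'   `ee_kcal` is absent.
#' @param variants Schofield variants to evaluate.
#' @return List with `table` (one row per combination), `log_convention`,
#'   `variant` and `model` (the bundled model under the selected convention).
#' @export
calibrate_log_convention <- function(persons, target_pct = NULL,
                                     variants = c("fao_kcal",
                                                  "schofield_mj")) {
  if ("ee_kcal" %in% names(persons) && any(!is.na(persons$ee_kcal))) {
    ok <- !is.na(persons$ee_kcal)
    target <- mean(pct_misreport(persons$ee_kcal[ok],
                                 persons$ei_claimed_kcal[ok]))
  } else if (!is.null(target_pct)) {
    target <- target_pct
  } else {
    stopf("persons has no ee_kcal; supply target_pct (observed mean percent misreporting)")
  }
  grid <- expand.grid(log_convention = c("natural", "base10"),
                      variant = variants, stringsAsFactors = FALSE)
  grid$mean_predicted <- NA_real_
  for (i in seq_len(nrow(grid))) {
    m <- default_open_model(grid$log_convention[i])
    grid$mean_predicted[i] <- mean(
      predict_pct_misreport(m, persons, variant = grid$variant[i]))
  }
  grid$abs_error <- abs(grid$mean_predicted - target)
  best <- which.min(grid$abs_error)
  list(table = grid, target_pct = target,
       log_convention = grid$log_convention[best],
       variant = grid$variant[best],
       model = default_open_model(grid$log_convention[best]))
}
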