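#' Apply survey exclusion rules to a raw person table
#'
#' Removes, in order: respondents on a special diet, those who did not eat
#' their typical diet that day, non-reporters (flagged, or with missing
#' claimed intake), and anyone under the minimum age of 18. A record failing
#' several rules is counted under the first rule that removes it. Missing
#' flag columns (or NA flags) are treated as FALSE.
#'
#' @param persons Raw person table; flag columns `special_diet`,
#'   `atypical_day`, `nonreporter` are optional logicals.
#' @param min_age Minimum age retained, default 18.
#' @return The filtered table, with an `exclusions` attribute giving the
#'   count removed per rule and the count retained.
#' @export
apply_exclusions <- function(persons, min_age = 18) {
  flag <- function(nm) {
    if (!nm %in% names(persons)) return(rep(FALSE, nrow(persons)))
    f <- persons[[nm]]
    if (!is.logical(f)) f <- as.logical(f)
    f & !is.na(f)
  }
  special <- flag("special_diet")
  atypical <- flag("atypical_day") & !special
  nonrep <- (flag("nonreporter") |
               (if ("ei_claimed_kcal" %in% names(persons))
                  is.na(persons$ei_claimed_kcal) else FALSE)) &
    !special & !atypical
  underage <- rep(FALSE, nrow(persons))
  if ("age_years" %in% names(persons)) {
    underage <- (is.na(persons$age_years) | persons$age_years < min_age) &
      !special & !atypical & !nonrep
  }
  keep <- !(special | atypical | nonrep | underage)
  out <- persons[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(special_diet = sum(special),
                               atypical_day = sum(atypical),
                               nonreporter = sum(nonrep),
                               under_age = sum(underage),
                               retained = sum(keep))
  out
}

#' Subset a population the way the correction models were trained
#'
#' @param persons Person table.
#' @param filter One of `"all_adults"` (no subsetting beyond exclusions),
#'   `"nonblack"` (drop `race_group == "black"`), or `"nonblack_40_69"`
#'   (additionally restrict to ages 40-69, the training-cohort age range).
#' @return The filtered table.
#' @export
filter_population <- function(persons,
                              filter = c("all_adults", "nonblack",
                                         "nonblack_40_69")) {
  filter <- match.arg(filter)
  if (filter == "all_adults") return(persons)
  if (!"race_group" %in% names(persons)) {
    stopf("race filter requested but person table has no race_group column")
  }
  persons <- persons[persons$race_group != "black" |
                       is.na(persons$race_group), , drop = FALSE]
  if (filter == "nonblack_40_69") {
    persons <- persons[persons$age_years >= 40 & persons$age_years <= 69, ,
                       drop = FALSE]
  }
  persons
}

age_bin_labels <- function(edges) {
  n <- length(edges)
  c(if (n > 1) sprintf("[%g,%g)", edges[-n], edges[-1]),
    sprintf("[%g,Inf)", edges[n]))
}

assign_age_bin <- function(age, edges) {
  labs <- age_bin_labels(edges)
  idx <- findInterval(age, edges)   # half-open [lo, hi); top bin unbounded
  if (any(idx == 0)) stopf("ages below the first bin edge (%g)", edges[1])
  labs[idx]
}

#' Partition a person table into age-sex strata
#'
#' Builds the sex-by-age-bin strata from which simulated populations are
#' resampled. Age bins are half-open `[lo, hi)` (an age exactly on an
#' interior edge goes to the upper bin); ages at or above the last edge go
#' to the final, unbounded bin.
#'
#' @param persons Non-empty person table with `sex` and `age_years`.
#' @param age_bin_edges Strictly increasing lower bin edges in years;
#'   default decadal bins from 18.
#' @return Object of class `stratum_table`: list with `strata` (named list
#'   of data frames keyed `"sex|bin"`), `age_bin_edges` and `labels`.
#' @export
build_strata <- function(persons, age_bin_edges = c(18, 30, 40, 50, 60, 70)) {
  if (!nrow(persons)) stopf("person table must be non-empty")
  require_columns(persons, c("sex", "age_years"), "person table")
  if (length(age_bin_edges) < 1 || is.unsorted(age_bin_edges, strictly = TRUE)) {
    stopf("age_bin_edges must be strictly increasing")
  }
  persons$sex <- canonical_sex(persons$sex)
  bin <- assign_age_bin(persons$age_years, age_bin_edges)
  key <- paste(persons$sex, bin, sep = "|")
  structure(list(strata = split(persons, key),
                 age_bin_edges = age_bin_edges,
                 labels = age_bin_labels(age_bin_edges)),
            class = "stratum_table")
}

#' @export
print.stratum_table <- function(x, ...) {
  sizes <- vapply(x$strata, nrow, integer(1))
  cat("Age-sex stratum table:", length(sizes), "non-empty strata,",
      sum(sizes), "records\n")
  print(sizes)
  invisible(x)
}

#' Resample a synthetic survey population from age-sex strata
#'
#' Each simulated individual first receives an age-sex cell drawn from the
#' supplied probability table (e.g. a census age-sex distribution), then a
#' complete record (age, height, weight, claimed intake drawn jointly) is
#' sampled uniformly with replacement from that cell's stratum. Joint
#' whole-record resampling preserves the within-person correlation between
#' weight and intake.
#'
#' @param strata A [build_strata()] result.
#' @param weights Data frame with columns `sex`, `age_bin`, `weight`;
#'   weights must be non-negative and sum to 1 (tolerance 1e-9), and every
#'   positively weighted cell must have a non-empty stratum.
#' @param n Number of individuals to draw.
#' @param seed Optional integer seed; the same seed yields the identical
#'   population. The caller's RNG state is preserved.
#' @return Person table of `n` rows (stratum columns plus `age_bin`).
#' @export
sample_population <- function(strata, weights, n, seed = NULL) {
  stopifnot(inherits(strata, "stratum_table"))
  require_columns(weights, c("sex", "age_bin", "weight"), "weights table")
  if (!is_count(n)) stopf("n must be a positive integer")
  w <- weights$weight
  if (any(w < 0)) stopf("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stopf("weights must sum to 1 (got %.12f)", sum(w))
  keys <- paste(canonical_sex(weights$sex), weights$age_bin, sep = "|")
  pos <- which(w > 0)
  missing <- pos[!keys[pos] %in% names(strata$strata)]
  if (length(missing)) {
    stopf("positively weighted cell(s) with empty stratum: %s",
          paste(keys[missing], collapse = ", "))
  }
  with_seed(seed, {
    cell <- sample.int(length(w), n, replace = TRUE, prob = w)
    row_of <- integer(n)
    for (ci in unique(cell)) {
      take <- which(cell == ci)
      stratum_n <- nrow(strata$strata[[keys[ci]]])
      row_of[take] <- sample.int(stratum_n, length(take), replace = TRUE)
    }
    pieces <- lapply(unique(cell), function(ci) {
      take <- which(cell == ci)
      rec <- strata$strata[[keys[ci]]][row_of[take], , drop = FALSE]
      rec$age_bin <- weights$age_bin[ci]
      rec$.order <- take
      rec
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$.order), , drop = FALSE]
    out$.order <- NULL
    rownames(out) <- NULL
    out
  })
}

#' Simulation configuration
#'
#' @param n_individuals Individuals per replicate (default 10,000).
#' @param n_replicates Number of Monte-Carlo replicates (default 1,000).
#' @param seed Master seed; per-replicate seeds are derived from it so each
#'   replicate is an independent, individually reproducible stream.
#' @param method Correction applied to each simulated population: `"none"`
#'   (baseline), `"regression"` or `"intake_shift"`.
#' @param population_filter Metadata recording which source subset the
#'   strata were built from (see [filter_population()]).
#' @param bounds Plausibility bounds used for the failure rate.
#' @param variant Schofield RMR variant.
#' @param cap_pct Clamp on predicted misreporting before inversion.
#' @param max_pooled_deltas Memory guard: regression per-person deltas are
#'   pooled across replicates up to this many values (systematic
#'   per-replicate subsampling beyond).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 10000, n_replicates = 1000,
                              seed = 1,
                              method = c("none", "regression", "intake_shift"),
                              population_filter = c("all_adults", "nonblack",
                                                    "nonblack_40_69"),
                              bounds = plausibility_bounds(),
                              variant = "fao_kcal", cap_pct = 99,
                              max_pooled_deltas = 2e6) {
  if (!is_count(n_individuals) || !is_count(n_replicates)) {
    stopf("n_individuals and n_replicates must be positive integers")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_replicates = as.integer(n_replicates),
                 seed = seed, method = match.arg(method),
                 population_filter = match.arg(population_filter),
                 bounds = bounds, variant = variant, cap_pct = cap_pct,
                 max_pooled_deltas = max_pooled_deltas),
            class = "simulation_config")
}

#' Monte-Carlo simulation of a survey population under a correction method
#'
#' For each replicate: resample a population of `n_individuals` from the
#' age-sex strata, derive RMR and the claimed energy-intake index, apply the
#' configured correction (none, regression inversion, or per-sex intake
#' shift), classify each individual against the plausibility bounds, and
#' record the percent implausible. The failure rate is evaluated on the
#' corrected index for both corrections and on the raw claimed index for the
#' baseline.
#'
#' @param config A [simulation_config()].
#' @param strata A [build_strata()] result.
#' @param weights Age-sex cell probabilities, see [sample_population()].
#' @param model A [misreport_model()]; required iff
#'   `config$method == "regression"`.
#' @param pal Named list with elements `male` and/or `female` of
#'   [pal_distribution()]s; required iff `config$method == "intake_shift"`.
#' @return Object of class `simulation_result`: per-replicate failure rates
#'   and their mean; for the intake shift, per-sex shifts (per replicate and
#'   averaged); for the regression, pooled 25th/75th percentiles of the
#'   per-person caloric adjustment.
#' @export
run_simulation <- function(config, strata, weights, model = NULL, pal = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$method == "regression" && !inherits(model, "misreport_model")) {
    stopf("method 'regression' requires a misreport_model")
  }
  if (config$method == "intake_shift") {
    ok <- is.list(pal) && length(pal) &&
      all(vapply(pal, inherits, logical(1), "pal_distribution"))
    if (!ok) stopf("method 'intake_shift' requires a named list of pal_distribution objects")
  }
  if (config$method == "none" && (!is.null(model) || !is.null(pal))) {
    stopf("method 'none' takes neither a model nor PAL distributions")
  }

  n_rep <- config$n_replicates
  rep_seeds <- with_seed(config$seed,
                         sample.int(2147483646L, n_rep, replace = FALSE))
  fail <- numeric(n_rep)
  shift_by_sex <- NULL
  deltas <- list()
  per_rep_delta_cap <- max(1L, floor(config$max_pooled_deltas / n_rep))

  for (r in seq_len(n_rep)) {
    pop <- sample_population(strata, weights, config$n_individuals,
                             seed = rep_seeds[r])
    sex <- canonical_sex(pop$sex)
    rmr <- schofield_rmr(sex, pop$age_years, pop$weight_kg,
                         variant = config$variant)
    ei <- pop$ei_claimed_kcal
    ind <- ei / rmr

    if (config$method == "none") {
      status <- classify_plausibility(ind, sex, config$bounds)
    } else if (config$method == "regression") {
      pct <- predict_pct_misreport(model, pop, rmr_kcal = rmr)
      ei_corr <- correct_ei(ei, pct, cap = config$cap_pct)
      status <- classify_plausibility(ei_corr / rmr, sex, config$bounds)
      d <- ei_corr - ei
      if (length(d) > per_rep_delta_cap) {
        d <- d[seq(1L, length(d), length.out = per_rep_delta_cap)]
      }
      deltas[[r]] <- d
    } else {  # intake_shift
      ei_adj <- ei
      if (is.null(shift_by_sex)) {
        shift_by_sex <- matrix(NA_real_, n_rep, length(pal),
                               dimnames = list(NULL, names(pal)))
      }
      for (s in names(pal)) {
        rows <- which(sex == s)
        if (!length(rows)) next
        sh <- compute_shift(data.frame(ind_ei_claimed = ind[rows],
                                       rmr_kcal = rmr[rows]), pal[[s]])
        ei_adj[rows] <- apply_shift(ei[rows], sh$shift_kcal)
        shift_by_sex[r, s] <- sh$shift_kcal
      }
      status <- classify_plausibility(ei_adj / rmr, sex, config$bounds)
    }
    fail[r] <- 100 * mean(status != "plausible")
  }

  res <- list(method = config$method,
              failure_rate_per_replicate = fail,
              failure_rate_mean = mean(fail),
              n_individuals = config$n_individuals,
              n_replicates = n_rep,
              config = config)
  if (config$method == "intake_shift") {
    res$shift_kcal_by_sex <- list(per_replicate = shift_by_sex,
                                  mean = colMeans(shift_by_sex, na.rm = TRUE))
  }
  if (config$method == "regression") {
    pooled <- unlist(deltas, use.names = FALSE)
    res$delta_ei_quantiles <- stats::quantile(pooled, c(0.25, 0.75),
                                              names = FALSE)
    names(res$delta_ei_quantiles) <- c("p25", "p75")
  }
  structure(res, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulation (%s): %d replicates x %d individuals\n  mean failure rate: %.2f%%\n",
    x$method, x$n_replicates, x$n_individuals, x$failure_rate_mean))
  if (!is.null(x$shift_kcal_by_sex)) {
    m <- x$shift_kcal_by_sex$mean
    cat("  mean shift:",
        paste(sprintf("%s %+.0f kcal", names(m), m), collapse = ", "), "\n")
  }
  if (!is.null(x$delta_ei_quantiles)) {
    cat(sprintf("  per-person adjustment quartiles: %.0f / %.0f kcal\n",
                x$delta_ei_quantiles[["p25"]], x$delta_ei_quantiles[["p75"]]))
  }
  invisible(x)
}
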