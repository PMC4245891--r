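# CSV/JSON interchange. CSV is the single tabular format (survey-native SAS
# transport ingestion is out of scope; convert upstream); models,
# distributions and simulation results travel as JSON at full precision.

PERSON_NUMERIC <- c("age_years", "weight_kg", "height_cm",
                    "ei_claimed_kcal", "ee_kcal")
PERSON_FLAGS <- c("special_diet", "atypical_day", "nonreporter")

#' Read a person table from CSV
#'
#' Expects a header; canonical columns are `id`, `sex`, `age_years`,
#' `weight_kg`, `height_cm`, `ei_claimed_kcal`, `ee_kcal`, `special_diet`,
#' `atypical_day`, `nonreporter`, `race_group` (`age` is accepted as an
#' alias for `age_years`). `sex`, `age_years`, `weight_kg` and
#' `ei_claimed_kcal` are mandatory. Sex encodings 1/2, M/F and male/female
#' are mapped to the canonical coding; missing optional fields may be empty
#' cells. Per-column missingness is attached as the `missingness` attribute.
#'
#' @param path CSV file path.
#' @return Person data frame.
#' @export
read_person_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  if (!nrow(raw)) stopf("empty person table: %s", path)
  if ("age" %in% names(raw) && !"age_years" %in% names(raw)) {
    names(raw)[names(raw) == "age"] <- "age_years"
  }
  for (col in c("sex", "age_years", "weight_kg", "ei_claimed_kcal")) {
    if (!col %in% names(raw)) stopf("%s required", col)
  }
  out <- raw
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  for (col in intersect(PERSON_NUMERIC, names(out))) {
    v <- trimws(out[[col]])
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!blank(v) & is.na(num))
    if (length(bad)) {
      stopf("unparseable numeric in column %s, row %d: '%s'",
            col, bad[1], v[bad[1]])
    }
    out[[col]] <- num
  }
  for (col in intersect(PERSON_FLAGS, names(out))) {
    v <- tolower(trimws(out[[col]]))
    lg <- rep(NA, length(v))
    lg[v %in% c("true", "t", "1", "yes")] <- TRUE
    lg[v %in% c("false", "f", "0", "no") | blank(out[[col]])] <- FALSE
    bad <- which(is.na(lg))
    if (length(bad)) {
      stopf("unparseable flag in column %s, row %d: '%s'", col, bad[1],
            out[[col]][bad[1]])
    }
    out[[col]] <- lg
  }
  out$sex[blank(out$sex)] <- NA
  out$sex <- canonical_sex(out$sex)
  if ("race_group" %in% names(out)) {
    out$race_group[blank(out$race_group)] <- "unknown"
    out$race_group <- tolower(out$race_group)
    known <- c("black", "nonblack", "unknown")
    if (!all(out$race_group %in% known)) {
      stopf("race_group values must be one of %s", paste(known, collapse = ", "))
    }
  }
  miss <- vapply(out, function(x) sum(is.na(x)), integer(1))
  attr(out, "missingness") <- miss
  out
}

#' Write a person table to CSV
#'
#' @param persons Person data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_person_table <- function(persons, path) {
  out <- persons
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # %.17g keeps doubles bit-exact across a write/read round trip
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize / deserialize a misreporting model as JSON
#'
#' @param model A [misreport_model()].
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` the reconstructed [misreport_model()].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "misreport_model"))
  payload <- model[c("intercept", "beta_sex", "beta_age", "beta_weight",
                     "beta_log_ei", "beta_ind_ei", "log_convention",
                     "r_squared", "source")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  misreport_model(p$intercept, p$beta_sex, p$beta_age, p$beta_weight,
                  p$beta_log_ei, p$beta_ind_ei,
                  log_convention = p$log_convention,
                  r_squared = p$r_squared, source = p$source)
}

#' Serialize / deserialize PAL distributions as JSON
#'
#' Accepts a single [pal_distribution()] or a named list of them (one per
#' sex); the file round-trips to the same structure.
#'
#' @param pal A [pal_distribution()] or named list of them.
#' @param path JSON file path.
#' @export
write_pal_json <- function(pal, path) {
  if (inherits(pal, "pal_distribution")) pal <- list(pal)
  payload <- lapply(pal, function(d) {
    stopifnot(inherits(d, "pal_distribution"))
    list(sex = d$sex, log_mean = d$log_mean, log_sd = d$log_sd,
         n_source = d$n_source)
  })
  names(payload) <- vapply(payload, `[[`, character(1), "sex")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pal_json
#' @export
read_pal_json <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(p, function(d) {
    pal_distribution(d$sex, d$log_mean, d$log_sd,
                     n_source = d$n_source %||% NA_integer_)
  })
  names(out) <- vapply(out, `[[`, character(1), "sex")
  out
}

#' Write and read simulation results
#'
#' The structured result is written as JSON at full numeric precision;
#' optionally the per-replicate failure rates (and per-sex shifts, when
#' present) go to a companion CSV.
#'
#' @param result A `simulation_result` from [run_simulation()].
#' @param path JSON output path.
#' @param replicates_csv Optional CSV path for per-replicate values.
#' @export
write_simulation_result <- function(result, path, replicates_csv = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  if (dir.exists(path)) stopf("output path is a directory: %s", path)
  payload <- list(
    method = result$method,
    n_individuals = result$n_individuals,
    n_replicates = result$n_replicates,
    failure_rate_mean = result$failure_rate_mean,
    failure_rate_per_replicate = result$failure_rate_per_replicate
  )
  if (!is.null(result$shift_kcal_by_sex)) {
    payload$shift_kcal_mean <- as.list(result$shift_kcal_by_sex$mean)
    payload$shift_kcal_per_replicate <-
      as.data.frame(result$shift_kcal_by_sex$per_replicate)
  }
  if (!is.null(result$delta_ei_quantiles)) {
    payload$delta_ei_quantiles <- as.list(result$delta_ei_quantiles)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(replicates_csv)) {
    reps <- data.frame(replicate = seq_len(result$n_replicates),
                       failure_rate = result$failure_rate_per_replicate)
    if (!is.null(result$shift_kcal_by_sex)) {
      reps <- cbind(reps, result$shift_kcal_by_sex$per_replicate)
    }
    utils::write.csv(reps, replicates_csv, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_simulation_result
#' @export
read_simulation_result <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- list(method = p$method,
              failure_rate_per_replicate = p$failure_rate_per_replicate,
              failure_rate_mean = p$failure_rate_mean,
              n_individuals = p$n_individuals,
              n_replicates = p$n_replicates)
  if (!is.null(p$shift_kcal_mean)) {
    res$shift_kcal_by_sex <- list(
      per_replicate = as.matrix(p$shift_kcal_per_replicate),
      mean = unlist(p$shift_kcal_mean))
  }
  if (!is.null(p$delta_ei_quantiles)) {
    res$delta_ei_quantiles <- unlist(p$delta_ei_quantiles)
  }
  structure(res, class = "simulation_result")
}

#' Write a run log for a command-line invocation
#'
#' Records the timestamp, command, effective configuration, master seed,
#' package version and MD5 digests of the input/output files, so that any
#' run can be reproduced and verified.
#'
#' @param path Log path (JSON).
#' @param command Subcommand name.
#' @param config Named list echoing the effective configuration.
#' @param seed Master seed (may be NULL).
#' @param files Character vector of input/output paths to digest.
#' @export
write_run_log <- function(path, command, config = list(), seed = NULL,
                          files = character()) {
  files <- files[file.exists(files)]
  digests <- if (length(files)) as.list(tools::md5sum(files)) else NULL
  payload <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  command = command, config = config, seed = seed,
                  package_version = as.character(utils::packageVersion("eicorrect")),
                  file_digests = digests)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
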