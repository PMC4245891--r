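# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL runs code unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is_count(seed + 1)) stopf("seed must be a single non-negative integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Canonical sex coding. Survey files encode sex as 1/2, M/F or male/female;
# internally "male"/"female" is used, with numeric code 1 = male, 2 = female
# (the coding under which the bundled regression coefficients apply).
canonical_sex <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !x %in% c(1, 2)
    if (any(bad, na.rm = TRUE)) {
      stopf("numeric sex codes must be 1 (male) or 2 (female); got %s",
            paste(unique(x[bad]), collapse = ", "))
    }
    return(c("male", "female")[x])
  }
  key <- tolower(trimws(as.character(x)))
  map <- c("1" = "male", "2" = "female", "m" = "male", "f" = "female",
           "male" = "male", "female" = "female")
  out <- unname(map[key])
  if (anyNA(out[!is.na(key)])) {
    bad <- unique(key[is.na(unname(map[key])) & !is.na(key)])
    stopf("unrecognised sex value(s): %s", paste(bad, collapse = ", "))
  }
  out
}

sex_code <- function(x) ifelse(canonical_sex(x) == "male", 1, 2)

# Exact draws from a normal truncated below at `lower` (inverse-CDF method).
rnorm_trunc <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, 1), mean, sd)
}

# Mean and SD of a normal(mu, sigma) truncated below at `lower`.
trunc_norm_moments <- function(mu, sigma, lower) {
  a <- (lower - mu) / sigma
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + a * lambda - lambda^2)
  c(mean = m, sd = sqrt(v))
}

# Parent (mu, sigma) such that the normal truncated below at `lower` has the
# requested mean and SD. Keeps generated samples on-target even when the
# truncation point carries non-trivial mass.
trunc_norm_params <- function(target_mean, target_sd, lower) {
  if (target_sd <= 0) return(c(mu = target_mean, sigma = 0))
  if (target_mean <= lower) stopf("target mean must exceed the lower bound")
  obj <- function(par) {
    m <- trunc_norm_moments(par[1], exp(par[2]), lower)
    (m[["mean"]] - target_mean)^2 / target_sd^2 +
      (m[["sd"]] - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Moment-matched truncated-normal sampler.
rnorm_trunc_matched <- function(n, target_mean, target_sd, lower) {
  if (target_sd == 0) return(rep(target_mean, n))
  p <- trunc_norm_params(target_mean, target_sd, lower)
  rnorm_trunc(n, p[["mu"]], p[["sigma"]], lower)
}

# Log-normal parameters matched to an arithmetic mean and SD.
lognormal_params_from_moments <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

require_columns <- function(df, cols, context = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("%s required in %s", paste(missing, collapse = ", "), context)
  }
  invisible(df)
}
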