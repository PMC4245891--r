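test_that("the linear predictor matches hand arithmetic and is linear", {
  zero <- misreport_model(0, 0, 0, 0, 0, 0)
  p <- make_persons(3, sex = c("male", "female", "male"),
                    age = c(25, 50, 70), weight = c(60, 80, 95),
                    ei = c(1500, 2200, 3000))
  expect_equal(predict_pct_misreport(zero, p), rep(0, 3))

  # hand-computed dot product under the published coefficients
  m <- default_open_model()
  ei <- exp(7.6)
  person <- make_persons(1, sex = "female", age = 50, weight = 70, ei = ei)
  rmr <- ei / 1.3  # makes the intake index exactly 1.3
  expected <- 298.19 - 2.30 * 2 - 0.36 * 50 + 0.21 * 70 -
    35.84 * 7.6 - 30.47 * 1.3
  expect_equal(predict_pct_misreport(m, person, rmr_kcal = rmr), expected,
               tolerance = 1e-12)
  expect_equal(round(expected, 3), -21.705)

  # linearity: one extra year changes the prediction by exactly beta_age
  older <- person
  older$age_years <- 51
  expect_equal(predict_pct_misreport(m, older, rmr_kcal = rmr) -
                 predict_pct_misreport(m, person, rmr_kcal = rmr),
               m$beta_age, tolerance = 1e-10)

  expect_error(predict_pct_misreport(m, make_persons(1, ei = 0)), "positive")
})

test_that("base-10 and natural log conventions differ as expected", {
  p <- make_persons(1, sex = "male", age = 40, weight = 70, ei = 2000)
  d_nat <- predict_pct_misreport(default_open_model("natural"), p)
  d_b10 <- predict_pct_misreport(default_open_model("base10"), p)
  expect_equal(d_b10 - d_nat, -35.84 * (log10(2000) - log(2000)),
               tolerance = 1e-10)
})

test_that("correct_ei inverts misreporting and guards the denominator", {
  expect_equal(correct_ei(1500, 0), 1500)
  expect_equal(correct_ei(1000, 50), 2000)
  expect_equal(correct_ei(2346, pct_misreport(2627, 2346)), 2627)
  # clamping: an extreme prediction is capped before inversion
  expect_equal(correct_ei(100, 150), 100 / (1 - 0.99))
  expect_equal(correct_ei(1000, -250, cap = 200), 1000 / 3)
  expect_error(correct_ei(1000, 100, cap = 150), "below 100")
  expect_error(correct_ei(-5, 10), "non-negative")
})

test_that("correction only moves intake in the predicted direction", {
  m <- default_open_model()
  set.seed(31)
  p <- make_persons(200, sex = sample(c("male", "female"), 200, TRUE),
                    age = runif(200, 18, 79), weight = runif(200, 45, 130),
                    ei = runif(200, 400, 5000))
  pct <- predict_pct_misreport(m, p)
  corrected <- correct_ei(p$ei_claimed_kcal, pct)
  expect_true(all((corrected > p$ei_claimed_kcal) == (pct > 0)))
  expect_true(all(is.finite(corrected)))
})

test_that("refitting recovers generating coefficients on clean data", {
  truth <- default_open_model()
  tr <- generate_open_like(400, noise_sd = 0, seed = 19)
  fit <- suppressWarnings(fit_misreport_model(tr))
  for (nm in c("intercept", "beta_sex", "beta_age", "beta_weight",
               "beta_log_ei", "beta_ind_ei")) {
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-6)
  }
  expect_equal(fit$source, "refit")
  # bias shrinks with n under noise: estimates at n=500 vs n=5000
  est_err <- function(n) {
    f <- fit_misreport_model(generate_open_like(n, noise_sd = 5, seed = 77))
    abs(f$beta_log_ei - truth$beta_log_ei)
  }
  expect_lt(est_err(5000), est_err(500) + 0.5)
})

test_that("rank-deficient designs fail loudly naming the collinear term", {
  tr <- generate_open_like(100, seed = 5)
  tr$weight_kg <- 70  # constant column aliases with the intercept
  expect_error(fit_misreport_model(tr), "collinear")
  tr2 <- generate_open_like(100, seed = 5)
  tr2$dup <- tr2$weight_kg
  expect_error(
    backward_eliminate(tr2, candidates = c("sex_code", "weight_kg", "dup")),
    "collinear")
  expect_error(fit_misreport_model(generate_open_like(10, seed = 1)),
               "at least 20")
})

test_that("backward elimination keeps truly predictive covariates", {
  tr <- generate_open_like(2000, noise_sd = 5, seed = 23)
  sw <- backward_eliminate(tr)
  expect_setequal(sw$retained,
                  c("sex_code", "age_years", "weight_kg", "log_ei", "ind_ei"))
  expect_s3_class(sw$model, "misreport_model")
})

test_that("backward elimination drops the worst p-value first", {
  # two junk covariates: the one with the larger p in the full fit goes first
  tr <- generate_open_like(500, noise_sd = 5, seed = 29)
  set.seed(30)
  tr$junk_a <- rnorm(500)
  tr$junk_b <- rnorm(500)
  cand <- c("sex_code", "age_years", "weight_kg", "log_ei", "ind_ei",
            "junk_a", "junk_b")
  sw <- backward_eliminate(tr, candidates = cand)
  expect_false(any(c("junk_a", "junk_b") %in% sw$retained))
  # reproduce the full initial fit to identify the expected first victim
  d <- data.frame(pct = pct_misreport(tr$ee_kcal, tr$ei_claimed_kcal),
                  sex_code = ifelse(tr$sex == "male", 1, 2),
                  age_years = tr$age_years, weight_kg = tr$weight_kg,
                  log_ei = log(tr$ei_claimed_kcal),
                  ind_ei = tr$ei_claimed_kcal /
                    schofield_rmr(tr$sex, tr$age_years, tr$weight_kg),
                  junk_a = tr$junk_a, junk_b = tr$junk_b)
  pv <- summary(lm(pct ~ ., data = d))$coefficients[, 4]
  pv <- pv[setdiff(names(pv), "(Intercept)")]
  expect_equal(sw$trace$dropped[1], names(which.max(pv)))
})

test_that("the QQ diagnostic estimates spread for normal data", {
  set.seed(13)
  x <- rnorm(10000, mean = 10, sd = 7)
  qq <- normality_diagnostic(x)
  expect_equal(qq$slope, sd(x), tolerance = 0.02)
  expect_equal(qq$intercept, mean(x), tolerance = 0.05 * sd(x))
  qq_const <- normality_diagnostic(rep(4, 50))
  expect_equal(qq_const$slope, 0, tolerance = 1e-12)
  expect_true(all(qq_const$observed == 4))
  expect_error(normality_diagnostic(c(1, 2)), "at least 3")
})

test_that("log-convention calibration prefers the generating convention", {
  tr <- generate_open_like(4000, noise_sd = 5, seed = 53)
  cal <- calibrate_log_convention(tr)
  expect_equal(cal$log_convention, "natural")
  expect_equal(nrow(cal$table), 4L)
  nat <- cal$table$abs_error[cal$table$log_convention == "natural"]
  b10 <- cal$table$abs_error[cal$table$log_convention == "base10"]
  expect_true(all(nat < min(b10)))
  expect_error(calibrate_log_convention(make_persons(5)), "target_pct")
})

test_that("intercept recentring matches the requested mean exactly", {
  g <- generate_nhanes_like(2000, seed = 57)
  m <- recenter_model(default_open_model(), g$persons, target_pct = 10.7)
  expect_equal(mean(predict_pct_misreport(m, g$persons)), 10.7,
               tolerance = 1e-9)
  expect_equal(m$beta_log_ei, default_open_model()$beta_log_ei)
  expect_equal(m$source, "refit")
})

test_that("model JSON serialization round-trips", {
  path <- tempfile(fileext = ".json")
  m <- default_open_model()
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2[c("intercept", "beta_sex", "beta_age", "beta_weight",
                    "beta_log_ei", "beta_ind_ei", "log_convention",
                    "r_squared", "source")],
               m[c("intercept", "beta_sex", "beta_age", "beta_weight",
                   "beta_log_ei", "beta_ind_ei", "log_convention",
                   "r_squared", "source")])
})
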