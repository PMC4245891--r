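test_that("exclusion rules remove flagged, non-reporting and under-age rows", {
  raw <- data.frame(
    id = 1:6, sex = "female", age_years = c(40, 40, 40, 40, 17, 40),
    weight_kg = 70, ei_claimed_kcal = c(2000, 2000, 2000, NA, 2000, 2000),
    special_diet = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    atypical_day = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    nonreporter = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  out <- apply_exclusions(raw)
  expect_equal(out$id, 6L)
  counts <- attr(out, "exclusions")
  expect_equal(unname(counts[c("special_diet", "atypical_day", "nonreporter",
                               "under_age", "retained")]),
               c(1L, 1L, 2L, 1L, 1L))
  # missing flag columns are treated as FALSE
  clean <- data.frame(sex = "male", age_years = 30, weight_kg = 80,
                      ei_claimed_kcal = 2500)
  expect_equal(nrow(apply_exclusions(clean)), 1L)
})

test_that("population filters mirror the training subsets", {
  p <- data.frame(sex = "male", age_years = c(25, 45, 45, 80),
                  race_group = c("nonblack", "black", "unknown", "nonblack"))
  expect_equal(nrow(filter_population(p, "all_adults")), 4L)
  nb <- filter_population(p, "nonblack")
  expect_false("black" %in% nb$race_group)
  expect_equal(nrow(nb), 3L)
  expect_equal(filter_population(p, "nonblack_40_69")$age_years, 45)
})

test_that("strata partition by sex and half-open age bins", {
  p <- make_persons(4, sex = c("male", "male", "female", "female"),
                    age = c(25, 35, 25, 35))
  st <- build_strata(p, age_bin_edges = c(18, 30))
  expect_s3_class(st, "stratum_table")
  expect_equal(length(st$strata), 4L)
  expect_true(all(vapply(st$strata, nrow, integer(1)) == 1L))

  # age exactly on an interior edge goes to the upper bin
  edge <- make_persons(1, sex = "male", age = 30)
  st2 <- build_strata(edge, age_bin_edges = c(18, 30, 40))
  expect_equal(names(st2$strata), "male|[30,40)")
  # ages above the last edge land in the final unbounded bin
  old <- make_persons(1, sex = "female", age = 93)
  st3 <- build_strata(old, age_bin_edges = c(18, 70))
  expect_equal(names(st3$strata), "female|[70,Inf)")

  expect_error(build_strata(p, age_bin_edges = c(40, 30)), "increasing")
  expect_error(build_strata(p[0, ]), "non-empty")
})

test_that("population resampling is weighted, joint and reproducible", {
  p <- make_persons(6, sex = c("male", "male", "male", "female", "female",
                               "female"),
                    age = c(25, 25, 35, 25, 35, 35),
                    weight = c(70, 90, 80, 60, 65, 72),
                    ei = c(2500, 2600, 2400, 1800, 1900, 2000))
  st <- build_strata(p, age_bin_edges = c(18, 30))
  w <- data.frame(sex = c("male", "female"), age_bin = "[18,30)",
                  weight = c(0.6, 0.4))
  pop <- sample_population(st, w, 5000, seed = 2)
  expect_equal(nrow(pop), 5000L)
  expect_equal(mean(pop$sex == "male"), 0.6, tolerance = 0.02)
  # joint resampling: every (weight, ei) pair is one of the source records
  expect_true(all(paste(pop$weight_kg, pop$ei_claimed_kcal) %in%
                    paste(p$weight_kg, p$ei_claimed_kcal)))
  # determinism
  pop2 <- sample_population(st, w, 5000, seed = 2)
  expect_identical(pop, pop2)
  # degenerate weights draw everything from one cell
  w1 <- data.frame(sex = c("male", "female"), age_bin = "[18,30)",
                   weight = c(1, 0))
  all_male <- sample_population(st, w1, 100, seed = 3)
  expect_true(all(all_male$sex == "male"))

  expect_error(sample_population(st, transform(w, weight = c(0.6, 0.6)), 10),
               "sum to 1")
  w_bad <- data.frame(sex = "male", age_bin = "[80,Inf)", weight = 1)
  expect_error(sample_population(st, w_bad, 10), "empty stratum")
})

test_that("baseline simulation reproduces a constructed failure fraction", {
  # population built so exactly 30% of records are out of bounds
  n_src <- 1000
  sex <- rep(c("male", "female"), each = n_src / 2)
  rmr <- schofield_rmr(sex, 45, 80)
  ind <- rep(1.5, n_src)
  bad <- seq_len(0.3 * n_src)  # 30% forced implausibly low
  ind[bad] <- 0.5
  src <- data.frame(sex = sex, age_years = 45, weight_kg = 80,
                    ei_claimed_kcal = ind * rmr)
  st <- build_strata(src, age_bin_edges = 18)
  w <- data.frame(sex = c("male", "female"), age_bin = "[18,Inf)",
                  weight = c(0.5, 0.5))
  cfg <- simulation_config(n_individuals = 2000, n_replicates = 20, seed = 8,
                           method = "none")
  res <- run_simulation(cfg, st, w)
  expect_equal(res$failure_rate_mean, 30, tolerance = 0.05)  # percent scale
  expect_true(all(res$failure_rate_per_replicate >= 0 &
                    res$failure_rate_per_replicate <= 100))
  expect_equal(length(res$failure_rate_per_replicate), 20L)
  expect_equal(mean(res$failure_rate_per_replicate), res$failure_rate_mean)
})

test_that("a correction that lands everyone in bounds gives zero failures", {
  # degenerate PAL distribution + homogeneous population: every adjusted
  # index equals the geometric mean 1.5, so nothing is implausible
  src <- make_persons(10, sex = "male", age = 45, weight = 80, ei = 900)
  st <- build_strata(src, age_bin_edges = 18)
  w <- data.frame(sex = "male", age_bin = "[18,Inf)", weight = 1)
  pal <- list(male = pal_distribution("male", log(1.5), 0))
  cfg <- simulation_config(n_individuals = 500, n_replicates = 3, seed = 5,
                           method = "intake_shift")
  res <- run_simulation(cfg, st, w, pal = pal)
  expect_equal(res$failure_rate_mean, 0)
  expect_equal(unname(res$shift_kcal_by_sex$mean["male"]),
               1.5 * schofield_rmr("male", 45, 80) - 900, tolerance = 1e-9)
})

test_that("simulation results are bitwise reproducible for a given seed", {
  sv <- small_survey(n = 1000, seed = 21, target = 0.32)
  cfg <- simulation_config(n_individuals = 1000, n_replicates = 5, seed = 77,
                           method = "regression")
  r1 <- run_simulation(cfg, sv$strata, sv$weights, model = default_open_model())
  r2 <- run_simulation(cfg, sv$strata, sv$weights, model = default_open_model())
  expect_identical(r1$failure_rate_per_replicate, r2$failure_rate_per_replicate)
  expect_identical(r1$delta_ei_quantiles, r2$delta_ei_quantiles)
  # a different seed gives a different draw
  cfg2 <- simulation_config(n_individuals = 1000, n_replicates = 5, seed = 78,
                            method = "regression")
  r3 <- run_simulation(cfg2, sv$strata, sv$weights, model = default_open_model())
  expect_false(identical(r1$failure_rate_per_replicate,
                         r3$failure_rate_per_replicate))
})

test_that("method and inputs must be consistent", {
  sv <- small_survey(n = 500, seed = 22)
  cfg <- simulation_config(n_individuals = 100, n_replicates = 2,
                           method = "regression")
  expect_error(run_simulation(cfg, sv$strata, sv$weights), "misreport_model")
  cfg2 <- simulation_config(n_individuals = 100, n_replicates = 2,
                            method = "intake_shift")
  expect_error(run_simulation(cfg2, sv$strata, sv$weights),
               "pal_distribution")
  cfg3 <- simulation_config(n_individuals = 100, n_replicates = 2,
                            method = "none")
  expect_error(run_simulation(cfg3, sv$strata, sv$weights,
                              model = default_open_model()), "neither")
})

test_that("replicate-mean uncertainty shrinks like one over root replicates", {
  sv <- small_survey(n = 1000, seed = 23, target = 0.32)
  cfg <- simulation_config(n_individuals = 1000, n_replicates = 60, seed = 31,
                           method = "none")
  res <- run_simulation(cfg, sv$strata, sv$weights)
  f <- res$failure_rate_per_replicate
  block_means <- colMeans(matrix(f, nrow = 10))  # 6 disjoint 10-rep means
  predicted_se <- sd(f) / sqrt(10)
  expect_gt(sd(block_means) / predicted_se, 0.35)
  expect_lt(sd(block_means) / predicted_se, 2.8)
})

test_that("simulation result JSON round-trips", {
  sv <- small_survey(n = 500, seed = 24, target = 0.32)
  cfg <- simulation_config(n_individuals = 500, n_replicates = 4, seed = 1,
                           method = "intake_shift")
  res <- run_simulation(cfg, sv$strata, sv$weights, pal = default_pal_list())
  path <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  write_simulation_result(res, path, replicates_csv = csv)
  back <- read_simulation_result(path)
  expect_equal(back$failure_rate_per_replicate, res$failure_rate_per_replicate)
  expect_equal(back$failure_rate_mean, res$failure_rate_mean)
  expect_equal(unname(back$shift_kcal_by_sex$mean),
               unname(res$shift_kcal_by_sex$mean))
  reps <- read.csv(csv)
  expect_equal(nrow(reps), 4L)
  expect_error(write_simulation_result(res, tempdir()), "directory")
})
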