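# Small in-code fixtures shared across test files.

make_persons <- function(n = 4,
                         sex = rep(c("male", "female"), length.out = n),
                         age = rep(45, n),
                         weight = rep(75, n),
                         ei = rep(2000, n),
                         ee = NULL) {
  out <- data.frame(id = sprintf("p%03d", seq_len(n)), sex = sex,
                    age_years = age, weight_kg = weight,
                    height_cm = rep(170, n), ei_claimed_kcal = ei,
                    stringsAsFactors = FALSE)
  if (!is.null(ee)) out$ee_kcal <- ee
  out
}

default_pal_list <- function() {
  list(male = default_open_pal("male"), female = default_open_pal("female"))
}

# A stratum table + weights built from a fixed synthetic survey population.
small_survey <- function(n = 2000, seed = 101, target = NULL) {
  g <- generate_nhanes_like(n, flavor = "2007", seed = seed,
                            implausible_fraction_target = target)
  list(strata = g$strata, weights = default_agesex_weights("2007"),
       persons = g$persons)
}
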