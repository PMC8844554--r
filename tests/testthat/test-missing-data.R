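baseline_cohort <- function() {
  pat <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:6),
    arm = rep(c("active", "control"), 3),
    country_setting = c("UK", "UK", "UK", "UK", "US", "US"),
    age = c(60, 62, 64, 66, 68, 70),
    sex = c("female", "female", "female", "male", "male", "male"),
    diabetes_duration = 10, smoking = c("never", "never", "current",
                                        NA, "former", NA),
    height = c(160, 170, NA, 180, 178, 176),
    weight = c(70, 72, 74, NA, 90, 92),
    prior_cvd = FALSE, followup_end = 3, death_time = NA_real_)
  ut <- tibble::tibble(
    patient_id = pat$patient_id, visit_time = 0, instrument = "EQ5D3L",
    mobility = 1L, self_care = 1L, usual_activities = 1L,
    pain_discomfort = 1L, anxiety_depression = 1L,
    utility = c(0.9, 0.7, NA, 0.8, NA, 0.6))
  mini_cohort(pat, utilities = ut)
}

test_that("baseline imputation follows the sex-mean and country-mode rules", {
  co <- impute_baseline(baseline_cohort())
  p <- co$patients
  # female heights observed {160, 170}; the missing female gets 165
  expect_equal(p$height[3], 165)
  # male weights observed {90, 92}; the missing male gets 91
  expect_equal(p$weight[4], 91)
  # UK smoking mode over {never, never, current} is "never"
  expect_equal(p$smoking[4], "never")
  # US smoking: only "former" observed
  expect_equal(p$smoking[6], "former")
  # baseline utilities by sex mean: female mean(0.9, 0.7) = 0.8
  expect_equal(co$utilities$utility[3], 0.8)
  expect_equal(co$utilities$utility[5], mean(c(0.8, 0.6)))
  # observed cells untouched
  expect_equal(p$height[c(1, 2, 4, 5, 6)], c(160, 170, 180, 178, 176))
})

test_that("an empty sex stratum falls back to the overall mean with a message", {
  co <- baseline_cohort()
  co$patients$height[co$patients$sex == "male"] <- NA  # no observed males
  expect_message(out <- impute_baseline(co), "overall mean")
  expect_equal(unique(out$patients$height[out$patients$sex == "male"]),
               mean(c(160, 170)))
})

test_that("no missing baseline data is the identity", {
  co <- baseline_cohort()
  co$patients$height[3] <- 168
  co$patients$weight[4] <- 85
  co$patients$smoking[c(4, 6)] <- "never"
  co$utilities$utility[c(3, 5)] <- 0.75
  out <- impute_baseline(co)
  expect_identical(out$patients, co$patients)
  expect_identical(out$utilities, co$utilities)
})

chained_fixture <- function(n = 2000, seed = 31, hold_out = 1) {
  # utility truth: u = 0.9 - 0.01 * (age - 60) + eps, sd 0.01, two visits
  withr::with_seed(seed, {
    age <- runif(n, 40, 80)
    pat <- tibble::tibble(
      patient_id = sprintf("P%05d", 1:n),
      arm = sample(c("active", "control"), n, TRUE),
      country_setting = "US", age = age,
      sex = sample(c("male", "female"), n, TRUE),
      diabetes_duration = runif(n, 1, 20), smoking = "never",
      height = 170, weight = 80, prior_cvd = FALSE,
      followup_end = 3, death_time = NA_real_)
    truth <- function(a) 0.9 - 0.01 * (a - 60)
    ut <- purrr::map_dfr(c(0, 1), function(v) {
      tibble::tibble(patient_id = pat$patient_id, visit_time = v,
                     instrument = "EQ5D3L",
                     utility = truth(age) + rnorm(n, 0, 0.01))
    })
    held_true <- ut$utility[ut$visit_time == 1][hold_out]
    ut$utility[ut$visit_time == 1][hold_out] <- NA
    # a further random 10% missing at visit 1 so the chain has real work
    mis <- sample(setdiff(seq_len(n), hold_out), n %/% 10)
    ut$utility[ut$visit_time == 1][mis] <- NA
    list(cohort = mini_cohort(pat, utilities = ut), held_true = held_true,
         truth_fun = truth)
  })
}

test_that("chained PMM recovers a held-out utility and keeps observed cells", {
  fx <- chained_fixture()
  cfg <- imputation_config(m = 28, chained_iterations = 5, seed = 8)
  imps <- impute_chained(fx$cohort, cfg)
  expect_s3_class(imps, "cea_imputations")
  expect_length(imps$utilities, 28)

  hold <- purrr::map_dbl(imps$utilities, function(u) {
    u$utility[u$visit_time == 1][1]
  })
  expect_lt(abs(mean(hold) - fx$held_true), 0.05)

  # observed cells identical across all m copies; imputed flagged
  obs_idx <- !imps$utilities[[1]]$imputed
  for (k in c(2, 28)) {
    expect_identical(imps$utilities[[k]]$utility[obs_idx],
                     imps$utilities[[1]]$utility[obs_idx])
  }
  # PMM: every imputed value equals some observed donor value
  obs_vals <- fx$cohort$utilities$utility[
    !is.na(fx$cohort$utilities$utility) &
      fx$cohort$utilities$visit_time == 1]
  imp_vals <- imps$utilities[[1]]$utility[imps$utilities[[1]]$imputed]
  expect_true(all(imp_vals %in% obs_vals))
  expect_true(all(imp_vals >= min(obs_vals) & imp_vals <= max(obs_vals)))

  # between-imputation variance of imputed cells is positive
  imp_idx <- which(imps$utilities[[1]]$imputed)
  mat <- sapply(imps$utilities, function(u) u$utility[imp_idx])
  expect_gt(mean(apply(mat, 1, var)), 0)
})

test_that("imputation is seeded and the no-missing case is the identity", {
  fx <- chained_fixture(n = 300, seed = 7)
  cfg <- imputation_config(m = 2, chained_iterations = 3, seed = 5)
  a <- impute_chained(fx$cohort, cfg)
  b <- impute_chained(fx$cohort, cfg)
  expect_identical(a$utilities, b$utilities)
  cfg2 <- imputation_config(m = 2, chained_iterations = 3, seed = 6)
  c <- impute_chained(fx$cohort, cfg2)
  imp <- a$utilities[[1]]$imputed
  expect_false(identical(a$utilities[[1]]$utility[imp],
                         c$utilities[[1]]$utility[imp]))
  expect_identical(a$utilities[[1]]$utility[!imp],
                   c$utilities[[1]]$utility[!imp])

  # fully observed input: all m copies equal the input
  co <- baseline_cohort()
  co$patients$smoking[c(4, 6)] <- "never"
  co$patients$height[3] <- 168
  co$patients$weight[4] <- 85
  co$utilities$utility[c(3, 5)] <- 0.75
  imps <- impute_chained(co, imputation_config(m = 3, seed = 1))
  for (k in 1:3) {
    expect_identical(imps$utilities[[k]]$utility, co$utilities$utility)
    expect_false(any(imps$utilities[[k]]$imputed))
  }
})

test_that("risk-factor averaging keeps observed cells and averages imputed ones", {
  base <- tibble::tibble(patient_id = c("P1", "P1", "P2"),
                         visit_time = c(0, 1, 0), factor = "hba1c",
                         value = c(6.5, NA, 7.5),
                         imputed = c(FALSE, TRUE, FALSE))
  tabs <- purrr::map(c(7, 8, 9), function(v) {
    t <- base
    t$value[2] <- v
    t
  })
  avg <- average_risk_factor_imputations(tabs)
  expect_equal(avg$value[2], 8)
  expect_equal(avg$value[c(1, 3)], c(6.5, 7.5))
  # m = 1 is the identity on that completion
  one <- average_risk_factor_imputations(tabs[1])
  expect_equal(one$value, tabs[[1]]$value)
  # inconsistent shapes are an error
  broken <- tabs
  broken[[2]] <- broken[[2]][-1, ]
  expect_error(average_risk_factor_imputations(broken), "inconsistent")
})

test_that("the full imputation chain on generated data preserves observed cells", {
  cfg <- cohort_config(n_patients = 400, seed = 21)
  co <- apply_missingness(generate_cohort(cfg), cfg)
  d <- impute_baseline(add_utility_values(co, default_value_set("US")))
  imps <- impute_chained(d, imputation_config(m = 3, chained_iterations = 3,
                                              seed = 2))
  rf_obs <- !imps$risk_factors[[1]]$imputed
  expect_identical(imps$risk_factors[[1]]$value[rf_obs],
                   d$risk_factors$value[rf_obs])
  expect_identical(imps$risk_factors[[2]]$value[rf_obs],
                   d$risk_factors$value[rf_obs])
  avg <- average_risk_factor_imputations(imps)
  expect_false(anyNA(avg$value))
  expect_identical(avg$value[rf_obs], d$risk_factors$value[rf_obs])
})
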