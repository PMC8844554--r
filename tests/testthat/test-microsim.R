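test_that("the hazard-to-probability bridge matches its closed forms", {
  eq <- make_equation("death", log(0.05))
  expect_equal(annual_event_probability(eq, list()), 1 - exp(-0.05))
  # vanishing hazard gives probability zero
  eq0 <- make_equation("death", -500)
  expect_equal(annual_event_probability(eq0, list()), 0)
  # weibull with shape 1 nests the exponential for any duration
  for (d in c(0, 3, 17.5)) {
    w <- make_equation("renal_failure", log(0.03), form = "weibull",
                       shape = 1)
    e <- make_equation("renal_failure", log(0.03))
    expect_equal(annual_event_probability(w, list(duration = d)),
                 annual_event_probability(e, list(duration = d)))
  }
  # logistic returns the fitted probability directly
  lg <- make_equation("mi", qlogis(0.2), form = "logistic")
  expect_equal(annual_event_probability(lg, list()), 0.2)
  # gompertz cumulative-hazard increment
  g <- make_equation("chf", log(0.01), form = "gompertz", shape = 0.1)
  t0 <- 5
  H <- function(t) 0.01 / 0.1 * (exp(0.1 * t) - 1)
  expect_equal(annual_event_probability(g, list(duration = t0)),
               1 - exp(-(H(t0 + 1) - H(t0))))
  # covariates shift the linear predictor around their reference values
  eq2 <- make_equation("mi", log(0.02),
                       extra = tibble::tibble(term = "hba1c",
                                              estimate = 0.1, ref = 8))
  expect_equal(annual_event_probability(eq2, list(hba1c = 8)),
               1 - exp(-0.02))
  expect_equal(annual_event_probability(eq2, list(hba1c = 10)),
               1 - exp(-0.02 * exp(0.2)))
  expect_error(annual_event_probability(eq2, list()), "lacks")
  # small hazards: p approximately lambda within 1% relative error
  for (lam in c(0.001, 0.01)) {
    p <- annual_event_probability(make_equation("mi", log(lam)), list())
    expect_lt(abs(p - lam) / lam, 0.01)
  }
})

test_that("profile updates age, duration and trajectories as configured", {
  prof <- tibble::tibble(age = 62, duration = 8, hba1c = 7.2, sbp = 130)
  p10 <- update_profile(prof, years = 10)
  expect_equal(p10$age, 72)
  expect_equal(p10$duration, 18)
  expect_equal(p10$hba1c, 7.2)         # held constant in the base case
  pd <- update_profile(prof, years = 10, trajectory_mode = "linear-drift",
                       drift = c(sbp = 0.1))
  expect_equal(pd$sbp, 131)
  expect_equal(pd$hba1c, 7.2)
  expect_error(update_profile(prof, trajectory_mode = "sideways"), "unknown")
})

test_that("treatment rules implement the discontinuation scenarios", {
  st <- tibble::tibble(on_drug = c(TRUE, TRUE, FALSE),
                       alive = c(TRUE, TRUE, TRUE),
                       hist_renal_failure = c(FALSE, TRUE, FALSE))
  cfg <- sim_config(scenario = "base", n_draws = 0)
  expect_equal(treatment_rule(st, "base", cfg), c(TRUE, FALSE, FALSE))
  expect_equal(treatment_rule(st, "scenario1", cfg), c(FALSE, FALSE, FALSE))
  # stop rate 0 nests the base case
  cfg2 <- sim_config(scenario = "scenario2", scenario2_stop_rate = 0,
                     n_draws = 0)
  expect_equal(treatment_rule(st, "scenario2", cfg2, year = 0,
                              stop_draws = c(0.5, 0.5, 0.5)),
               treatment_rule(st, "base", cfg))
  # stop rate 1 inside the window removes everyone
  cfg3 <- sim_config(scenario = "scenario2", scenario2_stop_rate = 1,
                     n_draws = 0)
  expect_equal(treatment_rule(st, "scenario2", cfg3, year = 0,
                              stop_draws = c(0.5, 0.5, 0.5)),
               c(FALSE, FALSE, FALSE))
  # outside the 10-year window no further stopping occurs
  expect_equal(treatment_rule(st, "scenario2", cfg3, year = 10,
                              stop_draws = c(0.5, 0.5, 0.5)),
               treatment_rule(st, "base", cfg))
  expect_error(treatment_rule(st, "scenario9", cfg), "unknown")
})

test_that("an event-free patient accrues the annuity exactly", {
  eq <- make_equation("death", -500)
  ct <- zero_cost_table()
  prof <- flat_profiles(1, utility = 0.8)
  cfg <- sim_config(horizon = 40, n_draws = 0, seed = 1, age_cap = 1e6,
                    discount_cost = 0, discount_effect = 0)
  out <- simulate_patient(prof, eq, ct, free_costing(), cfg)
  expect_equal(out$totals$life_years, 40)
  expect_equal(out$totals$qalys, 40 * 0.8)
  expect_equal(nrow(out$trace), 40)
  expect_true(all(out$trace$alive_end))

  cfg35 <- sim_config(horizon = 40, n_draws = 0, seed = 1, age_cap = 1e6,
                      discount_cost = 0.035, discount_effect = 0.035)
  out35 <- simulate_patient(prof, eq, ct, free_costing(), cfg35)
  annuity <- sum(1.035^-(0:39))
  expect_equal(out35$totals$life_years, annuity, tolerance = 1e-12)
  expect_equal(out35$totals$qalys, 0.8 * annuity, tolerance = 1e-12)
})

test_that("mortality-only simulation matches the discrete survival sum", {
  lam <- 0.1
  eq <- make_equation("death", log(lam))
  prof <- flat_profiles(4000, utility = 1)
  cfg <- sim_config(horizon = 100, n_draws = 0, seed = 2,
                    discount_cost = 0, discount_effect = 0, age_cap = 1e6)
  tot <- trialcea:::simulate_profiles(prof, eq, zero_cost_table(),
                                      free_costing(), cfg)
  p_year <- 1 - exp(-lam)
  expected <- sum((1 - p_year)^(0:99))
  se <- sd(tot$life_years) / sqrt(nrow(tot))
  expect_lt(abs(mean(tot$life_years) - expected), 3 * se)
})

test_that("a forced renal failure stops study-drug cost in its event year", {
  # renal failure certain once duration reaches 13 (extrapolation year 3)
  renal <- tibble::tibble(
    equation = "renal_failure", form = "logistic", shape = NA,
    term = c("intercept", "duration"), estimate = c(0, 1000),
    ref = c(0, 12.5))
  eq <- validate_risk_equations(dplyr::bind_rows(
    renal, tibble::tibble(equation = "death", form = "exponential",
                          shape = NA, term = "intercept", estimate = -500,
                          ref = 0)))
  cc <- free_costing()
  cc$eqw_price_per_dose <- 1          # 52.18 per on-drug year
  prof <- flat_profiles(1, duration = 10, on_drug = TRUE)
  cfg <- sim_config(horizon = 8, n_draws = 0, seed = 3,
                    discount_cost = 0, discount_effect = 0)
  out <- simulate_patient(prof, eq, zero_cost_table(), cc, cfg)
  tr <- out$trace
  expect_equal(tr$on_drug, c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
  expect_equal(tr$cost_therapy, c(rep(52.18, 3), rep(0, 5)))
  expect_equal(out$totals$cost_therapy, 3 * 52.18)
})

test_that("weibull shape one reproduces exponential traces under one seed", {
  ew <- make_equation("death", log(0.08), form = "weibull", shape = 1)
  ee <- make_equation("death", log(0.08))
  prof <- flat_profiles(500)
  cfg <- sim_config(horizon = 50, n_draws = 0, seed = 11,
                    discount_cost = 0, discount_effect = 0)
  tw <- trialcea:::simulate_profiles(prof, ew, zero_cost_table(),
                                     free_costing(), cfg)
  te <- trialcea:::simulate_profiles(prof, ee, zero_cost_table(),
                                     free_costing(), cfg)
  expect_equal(tw$life_years, te$life_years)
})

test_that("raising a hazard never increases coupled life-years", {
  prof <- flat_profiles(800)
  cfg <- sim_config(horizon = 60, n_draws = 0, seed = 19,
                    discount_cost = 0, discount_effect = 0)
  lo <- trialcea:::simulate_profiles(prof, make_equation("death", log(0.05)),
                                     zero_cost_table(), free_costing(), cfg)
  hi <- trialcea:::simulate_profiles(prof, make_equation("death", log(0.10)),
                                     zero_cost_table(), free_costing(), cfg)
  expect_true(all(hi$life_years <= lo$life_years + 1e-12))
})

test_that("discounted totals never exceed undiscounted ones", {
  cfg <- cohort_config(n_patients = 150, seed = 23)
  co <- generate_cohort(cfg)
  d <- add_utility_values(co, default_value_set("US"))
  prof <- end_of_trial_profiles(d)
  sc <- sim_config(horizon = 30, n_draws = 0, seed = 1)
  tot <- trialcea:::simulate_profiles(prof, default_risk_equations(),
                                      default_complication_table("US"),
                                      costing_config("US"), sc)
  expect_true(all(tot$life_years <= tot$life_years_undisc + 1e-9))
  expect_true(all(tot$qalys <= tot$qalys_undisc + 1e-9))
  expect_true(all(tot$cost_total <= tot$cost_total_undisc + 1e-9))
  expect_true(all(tot$qalys <= tot$life_years + 1e-9))
})

test_that("coefficient draws honour the covariance and reserve the point", {
  eq <- default_risk_equations()
  z <- draw_coefficients(eq, NULL, n_draws = 10, seed = 1)
  expect_length(z, 11)
  for (d in 2:11) expect_identical(z[[d]]$estimate, eq$estimate)

  ids <- paste(eq$equation, eq$term, sep = ":")[eq$term == "intercept"]
  S <- diag(0.01, length(ids))
  dimnames(S) <- list(ids, ids)
  dr <- draw_coefficients(eq, S, n_draws = 10000, seed = 2)
  expect_identical(dr[[1]]$estimate, eq$estimate)
  est <- sapply(dr[-1], function(e) e$estimate[match(ids[1], paste(
    e$equation, e$term, sep = ":"))])
  expect_lt(abs(var(est) - 0.01) / 0.01, 0.05)
  expect_equal(mean(est), eq$estimate[match(ids[1], ids)][1],
               tolerance = 0.01)
  # the contract size: 800 draws plus the reserved point set
  d800 <- draw_coefficients(eq, S, n_draws = 800, seed = 3)
  expect_length(d800, 801)
  # non-PSD covariance is rejected
  bad <- S
  bad[1, 1] <- -1
  expect_error(draw_coefficients(eq, bad, 5, 1), "semi-definite")
})

test_that("identical arms cancel exactly under common random numbers", {
  prof <- dplyr::bind_rows(flat_profiles(60, arm = "active"),
                           flat_profiles(60, arm = "control"))
  eq <- default_risk_equations()
  S <- default_coef_covariance(eq)
  cfg <- sim_config(horizon = 30, n_draws = 4, seed = 5)
  out <- simulate_cohort(prof, eq, default_complication_table("US"),
                         costing_config("US"), cfg, covariance = S)
  wide <- tidyr::pivot_wider(out, id_cols = "draw", names_from = "arm",
                             values_from = c("qalys", "cost_total",
                                             "life_years"))
  expect_equal(wide$qalys_active, wide$qalys_control, tolerance = 1e-12)
  expect_equal(wide$cost_total_active, wide$cost_total_control,
               tolerance = 1e-12)
  # one draw, one patient, forced event-free equals the patient-level run
  eq0 <- make_equation("death", -500)
  p1 <- flat_profiles(1, arm = "active")
  cfg1 <- sim_config(horizon = 10, n_draws = 0, seed = 9)
  a <- simulate_cohort(p1, eq0, zero_cost_table(), free_costing(), cfg1)
  b <- simulate_patient(p1, eq0, zero_cost_table(), free_costing(), cfg1)
  expect_equal(a$qalys, b$totals$qalys)
  expect_equal(a$life_years, b$totals$life_years)
  expect_error(simulate_cohort(prof[0, ], eq, zero_cost_table(),
                               free_costing(), cfg1), "empty")
})

test_that("a treatment coefficient yields a stable survival benefit", {
  lam <- 0.06
  eq <- make_equation("death", log(lam),
                      extra = tibble::tibble(term = "on_drug",
                                             estimate = log(0.8), ref = 0))
  prof <- dplyr::bind_rows(
    flat_profiles(2500, arm = "active", on_drug = TRUE),
    flat_profiles(2500, arm = "control", on_drug = FALSE))
  S <- matrix(0.002, 1, 1, dimnames = list("death:intercept",
                                           "death:intercept"))
  cfg <- sim_config(horizon = 80, n_draws = 40, seed = 6,
                    discount_cost = 0, discount_effect = 0, age_cap = 1e6)
  out <- simulate_cohort(prof, eq, zero_cost_table(), free_costing(), cfg,
                         covariance = S)
  wide <- tidyr::pivot_wider(out[out$draw > 0, ], id_cols = "draw",
                             names_from = "arm",
                             values_from = "life_years")
  dly <- wide$active - wide$control
  expect_gt(mean(dly), 0)
  expect_gte(mean(dly > 0), 0.95)
})

test_that("the small-instance event tree matches exhaustive enumeration", {
  p_mi <- 0.15
  p_death <- 0.10
  u0 <- 0.85
  eq <- validate_risk_equations(tibble::tibble(
    equation = c("mi", "death"), form = "logistic", shape = NA,
    term = "intercept", estimate = qlogis(c(p_mi, p_death)), ref = 0))
  ct <- zero_cost_table()
  ct[ct$complication == "mi", c("cost_event", "cost_ongoing",
                                "utility_event", "utility_ongoing")] <-
    list(1000, 200, 0.1, 0.05)
  cc <- free_costing()
  cc$background_annual <- 50
  prof <- flat_profiles(30000, utility = u0)
  cfg <- sim_config(horizon = 3, n_draws = 0, seed = 12,
                    discount_cost = 0.03, discount_effect = 0.03)
  tot <- trialcea:::simulate_profiles(prof, eq, ct, cc, cfg)
  oracle <- oracle_two_event_tree(p_mi, p_death, horizon = 3, u0 = u0,
                                  dec_event = 0.1, dec_ongoing = 0.05,
                                  cost_event = 1000, cost_ongoing = 200,
                                  background = 50, rate_cost = 0.03,
                                  rate_eff = 0.03)
  n <- nrow(tot)
  for (pair in list(list(got = tot$cost_total, want = oracle$cost),
                    list(got = tot$qalys, want = oracle$qaly),
                    list(got = tot$life_years, want = oracle$ly))) {
    se <- sqrt(pair$want["var"] / n)
    expect_lt(abs(mean(pair$got) - pair$want["mean"]), 3 * se)
  }
})
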