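fake_per_patient <- function(n = 200, imputations = 1, seed = 1,
                             sd_cost = 1000, sd_qaly = 0.3,
                             mean_cost_active = 11000,
                             mean_cost_control = 10000) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(imputations), function(k) {
      arm <- rep(c("active", "control"), each = n / 2)
      tibble::tibble(
        imputation = k, patient_id = sprintf("P%04d", seq_len(n)), arm = arm,
        baseline_utility = runif(n, 0.5, 1),
        qalys = 2 + 0.1 * (arm == "active") + rnorm(n, 0, sd_qaly),
        life_years = 3,
        therapy_cost = ifelse(arm == "active", 8000, 500),
        other_cost = ifelse(arm == "active", mean_cost_active - 8000,
                            mean_cost_control - 500) + rnorm(n, 0, sd_cost)) |>
        dplyr::mutate(total_cost = .data$therapy_cost + .data$other_cost)
    })
  })
}

test_that("bootstrap is seeded, stratified, and degenerate data collapse", {
  pp <- fake_per_patient(n = 100, imputations = 2)
  a <- bootstrap_within_trial(pp, B = 25, seed = 3)
  b <- bootstrap_within_trial(pp, B = 25, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a), 2 * 25)
  expect_setequal(unique(a$imputation), 1:2)

  # all patients identical within arm: every replicate equals the point
  pp2 <- fake_per_patient(n = 40, sd_cost = 0, sd_qaly = 0)
  pp2$baseline_utility <- 0.8
  r <- bootstrap_within_trial(pp2, B = 10, seed = 1)
  expect_equal(unique(round(r$dqaly, 12)), 0.1)
  expect_equal(unique(r$dcost), 1000)
})

test_that("bootstrap standard error tracks the closed-form two-sample SE", {
  n <- 400
  pp <- fake_per_patient(n = n, seed = 9, sd_cost = 2000)
  r <- bootstrap_within_trial(pp, B = 2000, seed = 5)
  act <- pp$arm == "active"
  se_closed <- sqrt(var(pp$total_cost[act]) / sum(act) +
                      var(pp$total_cost[!act]) / sum(!act))
  expect_lt(abs(sd(r$dcost) - se_closed) / se_closed, 0.15)
})

test_that("combining periods adds paired replicates and keeps the identity", {
  w <- tibble::tibble(imputation = 1, replicate = 1:3,
                      dcost = c(10, 10, 10), dqaly = c(0.01, 0.01, 0.01),
                      dly = 0.02)
  p <- tibble::tibble(draw = 0:3, dcost = c(99, 20, 21, 22),
                      dqaly = c(9, 0.02, 0.03, 0.04), dly = 0)
  out <- combine_periods(w, p)
  expect_equal(out$lifetime_dcost, c(30, 31, 32))
  expect_equal(out$lifetime_dqaly, c(0.03, 0.04, 0.05))
  expect_equal(out$lifetime_dcost, out$within_dcost + out$post_dcost)
  # all patients dead at trial end: zero post increments
  p0 <- tibble::tibble(draw = 0:3, dcost = 0, dqaly = 0, dly = 0)
  out0 <- combine_periods(w, p0)
  expect_equal(out0$lifetime_dcost, w$dcost)
  expect_equal(out0$lifetime_dqaly, w$dqaly)
  expect_error(combine_periods(w, p[p$draw == 0, ]), "no post-trial draws")
  expect_error(combine_periods(dplyr::mutate(w, replicate = 1:3 * 2), p),
               "fewer")
})

test_that("ICER handles quadrants, dominance and undefined ratios", {
  x <- icer(6357, 0.151)
  expect_equal(x$icer, 6357 / 0.151)
  expect_equal(round(x$icer, 1), 42099.3)
  expect_equal(x$quadrant, "NE")
  expect_equal(icer(-1, 0.1)$quadrant, "SE (dominant)")
  expect_true(is.na(icer(100, 0)$icer))
  expect_equal(icer(100, 0)$quadrant, "NW (dominated)")
  expect_equal(icer(-5, -0.1)$quadrant, "SW")
})

test_that("percentile bounds match a brute-force sorting oracle", {
  x <- as.numeric(1:1000)
  ci <- percentile_ci(x)
  expect_equal(unname(ci), c(25.975, 975.025))
  expect_equal(unname(ci),
               c(oracle_percentile(x, 0.025), oracle_percentile(x, 0.975)))
  withr::with_seed(4, {
    for (i in 1:20) {
      y <- rnorm(sample(41:500, 1))
      ci <- percentile_ci(y)
      expect_equal(unname(ci[1]), oracle_percentile(y, 0.025))
      expect_equal(unname(ci[2]), oracle_percentile(y, 0.975))
    }
  })
  cst <- percentile_ci(rep(7, 50))
  expect_equal(unname(cst), c(7, 7))
  # symmetric values give symmetric bounds
  z <- c(-(1:100), 1:100)
  cz <- percentile_ci(z)
  expect_equal(cz[[1]], -cz[[2]])
  expect_error(percentile_ci(numeric(0)), "no replicate")
})

test_that("the acceptability curve matches hand enumeration and is monotone", {
  rep1 <- tibble::tibble(lifetime_dcost = 10, lifetime_dqaly = 1)[rep(1, 5), ]
  cc <- ceac(rep1, thresholds = c(5, 20))
  expect_equal(cc$probability, c(0, 1))

  rows <- tibble::tibble(lifetime_dcost = c(10, 30, -5, 50, 20),
                         lifetime_dqaly = c(1, 1, 0.5, 2, -1))
  got <- ceac(rows, thresholds = c(0, 15, 40))
  hand <- vapply(c(0, 15, 40), function(l) {
    mean(l * rows$lifetime_dqaly - rows$lifetime_dcost > 0)
  }, numeric(1))
  expect_equal(got$probability, hand)

  # monotone with limit P(dQALY > 0) when effects are positive
  withr::with_seed(11, {
    pos <- tibble::tibble(lifetime_dcost = rnorm(500, 100, 50),
                          lifetime_dqaly = abs(rnorm(500, 0.1, 0.05)) + 1e-6)
    curve <- ceac(pos, thresholds = seq(0, 1e5, 1e3))
    expect_true(all(diff(curve$probability) >= 0))
    expect_equal(ceac(pos, thresholds = 1e9)$probability,
                 mean(pos$lifetime_dqaly > 0))
  })
})

test_that("currency rescaling scales the ICER and shifts the CEAC", {
  withr::with_seed(2, {
    reps <- tibble::tibble(lifetime_dcost = rnorm(400, 5000, 800),
                           lifetime_dqaly = rnorm(400, 0.1, 0.02))
  })
  k <- 1.38
  scaled <- dplyr::mutate(reps, lifetime_dcost = .data$lifetime_dcost * k)
  i1 <- icer(mean(reps$lifetime_dcost), mean(reps$lifetime_dqaly))$icer
  i2 <- icer(mean(scaled$lifetime_dcost), mean(scaled$lifetime_dqaly))$icer
  expect_equal(i2, k * i1)
  th <- seq(0, 2e5, 5e3)
  expect_equal(ceac(scaled, thresholds = th * k)$probability,
               ceac(reps, thresholds = th)$probability)
})

test_that("the lifetime table enforces its accounting identities", {
  comp <- tibble::tribble(
    ~quantity, ~period, ~arm, ~value,
    "therapy_cost", "within", "active", 100,
    "therapy_cost", "within", "control", 40,
    "other_cost", "within", "active", 60,
    "other_cost", "within", "control", 70,
    "therapy_cost", "post", "active", 300,
    "therapy_cost", "post", "control", 120,
    "other_cost", "post", "active", 500,
    "other_cost", "post", "control", 510,
    "qalys", "within", "active", 2.5,
    "qalys", "within", "control", 2.4,
    "qalys", "post", "active", 7.0,
    "qalys", "post", "control", 6.9)
  tab <- lifetime_table(comp)
  get <- function(q, p, col) tab[[col]][tab$quantity == q & tab$period == p]
  expect_equal(get("total_cost", "within", "active"), 160)
  expect_equal(get("total_cost", "lifetime", "active"), 960)
  expect_equal(get("therapy_cost", "lifetime", "difference"), 240)
  expect_equal(get("qalys", "lifetime", "active"), 9.5)
  # zero post components: lifetime equals within
  tab0 <- lifetime_table(comp[comp$period == "within", ])
  expect_equal(tab0$active[tab0$period == "lifetime"],
               tab0$active[tab0$period == "within"])
  # a supplied total that contradicts therapy + other is rejected
  bad <- dplyr::bind_rows(comp, tibble::tibble(
    quantity = "total_cost", period = "within", arm = "active", value = 150))
  expect_error(lifetime_table(bad), "inconsistent")
})

test_that("cloned-null data leave the acceptability curve near one half", {
  cfg <- cohort_config(n_patients = 500, seed = 33, mortality_hr_active = 1,
                       event_hazards = dplyr::mutate(default_event_hazards(),
                                                     hr_active = 1))
  co <- generate_cohort(cfg)
  # break any residual arm-outcome association entirely
  withr::with_seed(1, {
    co$patients$arm <- sample(co$patients$arm)
  })
  co$resource_use$study_drug_doses <- 0L
  ccfg <- cea_config("US", m = 2, B = 120, n_draws = 40, seed = 6)
  res <- run_cea(co, ccfg)
  mid <- res$ceac$probability[res$ceac$threshold == 1e5]
  expect_gt(mid, 0.15)
  expect_lt(mid, 0.85)
})
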