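## Synthetic two-arm trial cohort generator with known ground truth.

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a generated two-arm trial: sample
#' size, per-year event and mortality hazards with active-arm hazard ratios,
#' follow-up and dropout, the EQ-5D visit schedule, and the missingness
#' mechanism applied afterwards by [apply_missingness()].
#'
#' Defaults emulate a pragmatic cardiovascular-outcome trial in type 2
#' diabetes: median follow-up around 3.2 years with a 6.7-year maximum,
#' a modest all-cause mortality benefit in the active arm, annual EQ-5D
#' visits, and 28% missing post-baseline utility responses.
#'
#' @param n_patients Number of patients (both arms together).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param mortality_hazard_control Constant per-year all-cause mortality
#'   hazard in the control arm.
#' @param mortality_hr_active Active:control mortality hazard ratio.
#' @param event_hazards Data frame with columns `event`, `rate_control`
#'   (per-year hazard) and `hr_active`; events must be drawn from
#'   [complication_registry()].
#' @param missing_utility_rate Target fraction of post-baseline EQ-5D visit
#'   responses removed by [apply_missingness()].
#' @param missingness_mechanism `"MCAR"` or `"MAR"` (missing at random given
#'   baseline age: older patients more likely to skip the questionnaire).
#' @param baseline_missing_rates Named vector of removal rates for baseline
#'   `utility`, `height`, `weight` and `smoking`.
#' @param risk_factor_missing_rate Removal rate for post-baseline risk-factor
#'   measurements.
#' @param visit_schedule Scheduled EQ-5D / risk-factor visit times in years
#'   since randomization (0 = baseline).
#' @param dropout_rate Per-year hazard of loss to follow-up.
#' @param admin_censor_range Administrative censoring time drawn uniformly
#'   from this range (staggered entry into an event-driven trial).
#' @param prop_active Randomization fraction for the active arm.
#' @param prop_us Fraction of patients enrolled at US sites (`country_setting`).
#' @param prop_5l Fraction of patients assessed with EQ-5D-5L (others 3L).
#' @param utility_arm_effect Additive active-arm shift of the latent health
#'   score that drives generated EQ-5D profiles (0 = no direct effect).
#'
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 200, seed = 1)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_patients = 2000,
                          seed = 1,
                          mortality_hazard_control = 0.022,
                          mortality_hr_active = 0.86,
                          event_hazards = default_event_hazards(),
                          missing_utility_rate = 0.28,
                          missingness_mechanism = c("MCAR", "MAR"),
                          baseline_missing_rates = c(utility = 0.05,
                                                     height = 0.02,
                                                     weight = 0.02,
                                                     smoking = 0.03),
                          risk_factor_missing_rate = 0.10,
                          visit_schedule = 0:6,
                          dropout_rate = 0.04,
                          admin_censor_range = c(1.0, 6.7),
                          prop_active = 0.5,
                          prop_us = 0.5,
                          prop_5l = 0.7,
                          utility_arm_effect = 0) {
  missingness_mechanism <- match.arg(missingness_mechanism)
  if (!is_count(n_patients)) abort("`n_patients` must be a positive integer")
  if (!is_count(seed, positive = FALSE)) abort("`seed` must be an integer")
  if (mortality_hazard_control < 0) abort("mortality hazard must be >= 0")
  if (mortality_hr_active <= 0) abort("`mortality_hr_active` must be > 0")
  if (missing_utility_rate < 0 || missing_utility_rate >= 1) {
    abort("`missing_utility_rate` must lie in [0, 1)")
  }
  if (any(baseline_missing_rates < 0) || any(baseline_missing_rates >= 1)) {
    abort("baseline missing rates must lie in [0, 1)")
  }
  event_hazards <- tibble::as_tibble(event_hazards)
  stopifnot(all(c("event", "rate_control", "hr_active") %in% names(event_hazards)))
  bad <- setdiff(event_hazards$event, complication_registry())
  if (length(bad)) abort(paste0("unknown event(s): ", paste(bad, collapse = ", ")))
  if (any(event_hazards$rate_control < 0) || any(event_hazards$hr_active <= 0)) {
    abort("event hazards must be >= 0 and hazard ratios > 0")
  }
  if (length(visit_schedule) < 1 || is.unsorted(visit_schedule) ||
      any(visit_schedule < 0)) {
    abort("`visit_schedule` must be a sorted vector of non-negative times")
  }
  if (dropout_rate < 0) abort("`dropout_rate` must be >= 0")
  if (admin_censor_range[2] > 6.7 || admin_censor_range[1] <= 0) {
    abort("`admin_censor_range` must lie within (0, 6.7]")
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         mortality_hazard_control = mortality_hazard_control,
         mortality_hr_active = mortality_hr_active,
         event_hazards = event_hazards,
         missing_utility_rate = missing_utility_rate,
         missingness_mechanism = missingness_mechanism,
         baseline_missing_rates = baseline_missing_rates,
         risk_factor_missing_rate = risk_factor_missing_rate,
         visit_schedule = as.numeric(visit_schedule),
         dropout_rate = dropout_rate,
         admin_censor_range = admin_censor_range,
         prop_active = prop_active, prop_us = prop_us, prop_5l = prop_5l,
         utility_arm_effect = utility_arm_effect),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_event_hazards <- function() {
  tibble::tibble(
    event = c("mi", "stroke", "chf", "ihd", "renal_failure"),
    rate_control = c(0.012, 0.006, 0.008, 0.010, 0.004),
    hr_active = c(0.95, 0.95, 0.95, 0.95, 1.0))
}

#' Generate a synthetic two-arm trial cohort
#'
#' Simulates patient-level data with the structure a trial-based cost-utility
#' analysis consumes: baseline covariates and cardiovascular risk factors,
#' scheduled EQ-5D responses, annual resource-use records, non-fatal event
#' and death times, and arm assignment. All quantities are fully observed;
#' use [apply_missingness()] to null cells afterwards. The exact hazards and
#' effects used are returned in `ground_truth` so that recovery tests never
#' re-derive them.
#'
#' Event and death processes are competing exponential clocks; follow-up ends
#' at the earliest of death, dropout and administrative censoring. Times are
#' decimal years since randomization.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cea_cohort`: a list of tibbles `patients`,
#'   `utilities`, `resource_use`, `events`, `risk_factors`, plus a
#'   `ground_truth` list.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by `cohort_config()`")
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  id <- sprintf("P%05d", seq_len(n))
  arm <- ifelse(runif(n) < config$prop_active, "active", "control")
  country <- ifelse(runif(n) < config$prop_us, "US", "UK")
  age <- pmin(pmax(rnorm(n, 62, 8), 30), 90)
  sex <- ifelse(runif(n) < 0.62, "male", "female")
  duration <- pmin(rgamma_safe(n, shape = 2.8, scale = 4.6), 45)
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.45, 0.43, 0.12))
  height <- ifelse(sex == "male", rnorm(n, 176, 7), rnorm(n, 163, 7))
  bmi <- pmin(pmax(rnorm(n, 32, 6), 17), 60)
  weight <- bmi * (height / 100)^2
  prior_cvd <- runif(n) < 0.73

  # baseline continuous risk factors
  rf0 <- tibble::tibble(
    hba1c = pmax(rnorm(n, 8.0, 1.0), 5.0),
    sbp = pmax(rnorm(n, 135, 15), 85),
    ldl = pmax(rnorm(n, 2.3, 0.9), 0.4),
    hdl = pmax(rnorm(n, 1.1, 0.3), 0.3),
    bmi = bmi,
    heart_rate = pmax(rnorm(n, 75, 10), 40),
    egfr = pmin(pmax(rnorm(n, 76, 20), 10), 140))

  # survival: competing exponential clocks, arm-specific rates
  lam_death <- config$mortality_hazard_control *
    ifelse(arm == "active", config$mortality_hr_active, 1)
  death_all <- ifelse(lam_death > 0, rexp(n, pmax(lam_death, 1e-12)), Inf)
  admin <- runif(n, config$admin_censor_range[1], config$admin_censor_range[2])
  drop_t <- if (config$dropout_rate > 0) rexp(n, config$dropout_rate) else rep(Inf, n)
  censor <- pmin(admin, drop_t)
  followup_end <- pmin(death_all, censor)
  death_time <- ifelse(death_all <= censor, death_all, NA_real_)

  patients <- tibble::tibble(
    patient_id = id, arm = arm, country_setting = country,
    age = age, sex = sex, diabetes_duration = duration,
    smoking = smoking, height = height, weight = weight,
    prior_cvd = prior_cvd, followup_end = followup_end,
    death_time = death_time)

  # non-fatal events: one exponential clock each, first occurrence kept
  ev <- config$event_hazards
  events <- purrr::map_dfr(seq_len(nrow(ev)), function(i) {
    rate <- ev$rate_control[i] * ifelse(arm == "active", ev$hr_active[i], 1)
    t <- if (ev$rate_control[i] > 0) rexp(n, pmax(rate, 1e-12)) else rep(Inf, n)
    keep <- t <= followup_end
    tibble::tibble(patient_id = id[keep], event = ev$event[i], time = t[keep])
  })
  events <- dplyr::bind_rows(
    events,
    tibble::tibble(patient_id = id[!is.na(death_time)], event = "death",
                   time = death_time[!is.na(death_time)]))
  events <- dplyr::arrange(events, .data$patient_id, .data$time)

  # scheduled visits that occur within follow-up (baseline visit always kept)
  sched <- config$visit_schedule
  visits <- tidyr::expand_grid(idx = seq_len(n), visit_time = sched)
  visits <- dplyr::filter(visits, .data$visit_time <= followup_end[.data$idx] |
                            .data$visit_time == sched[1])
  visits$patient_id <- id[visits$idx]

  # latent health score drives both EQ-5D profiles and risk-factor drift
  frailty <- rnorm(n, 0, 0.06)
  s <- 0.88 - 0.004 * (age - 62) - 0.045 * prior_cvd -
    0.012 * (rf0$hba1c - 8) + frailty +
    ifelse(arm == "active", config$utility_arm_effect, 0)
  score <- s[visits$idx] - 0.006 * visits$visit_time +
    rnorm(nrow(visits), 0, 0.03)
  instrument <- ifelse(runif(n) < config$prop_5l, "EQ5D5L", "EQ5D3L")

  prof <- profile_from_score(score, instrument[visits$idx])
  utilities <- dplyr::bind_cols(
    tibble::tibble(patient_id = visits$patient_id,
                   visit_time = visits$visit_time,
                   instrument = instrument[visits$idx]),
    prof)
  utilities <- dplyr::arrange(utilities, .data$patient_id, .data$visit_time)

  # risk factors per visit: random walk around baseline
  rfl <- tidyr::expand_grid(idx = seq_len(n), visit_time = sched,
                            factor = risk_factor_registry())
  rfl <- dplyr::filter(rfl, .data$visit_time <= followup_end[.data$idx] |
                         .data$visit_time == sched[1])
  base_val <- as.matrix(rf0)[cbind(rfl$idx, match(rfl$factor, names(rf0)))]
  walk_sd <- c(hba1c = 0.25, sbp = 4, ldl = 0.2, hdl = 0.06, bmi = 0.5,
               heart_rate = 2.5, egfr = 3)[rfl$factor]
  risk_factors <- tibble::tibble(
    patient_id = id[rfl$idx], visit_time = rfl$visit_time,
    factor = rfl$factor,
    value = pmax(base_val + ifelse(rfl$visit_time > 0,
                                   rnorm(nrow(rfl), 0, walk_sd) *
                                     sqrt(rfl$visit_time), 0), 0.1))
  risk_factors <- dplyr::arrange(risk_factors, .data$patient_id,
                                 .data$factor, .data$visit_time)

  # annual resource-use periods clipped to follow-up
  ru <- tidyr::expand_grid(idx = seq_len(n), year = 0:6)
  ru <- dplyr::filter(ru, .data$year < followup_end[.data$idx])
  len <- pmin(followup_end[ru$idx] - ru$year, 1)
  compliance <- pmin(pmax(rnorm(n, 0.84, 0.10), 0), 1)
  on_active <- arm[ru$idx] == "active"
  resource_use <- tibble::tibble(
    patient_id = id[ru$idx],
    period_start = as.numeric(ru$year),
    period_end = ru$year + len,
    inpatient_days = rpois(nrow(ru), 0.55 * len *
                             ifelse(on_active, 0.92, 1) *
                             (1 + prior_cvd[ru$idx])),
    outpatient_visits = rpois(nrow(ru), 4 * len),
    conmed_units = rpois(nrow(ru), 300 * len * ifelse(on_active, 0.9, 1)),
    other_med_units = rpois(nrow(ru), 150 * len),
    study_drug_doses = ifelse(on_active,
                              round(52.18 * len * compliance[ru$idx]), 0L))
  resource_use <- dplyr::arrange(resource_use, .data$patient_id,
                                 .data$period_start)

  structure(
    list(patients = patients, utilities = utilities,
         resource_use = resource_use, events = events,
         risk_factors = risk_factors,
         ground_truth = list(
           config = config,
           mortality_hazard = c(control = config$mortality_hazard_control,
                                active = config$mortality_hazard_control *
                                  config$mortality_hr_active),
           event_hazards = ev, frailty_sd = 0.06,
           latent_score_model = "0.88 - 0.004(age-62) - 0.045 prior_cvd - 0.012(hba1c-8) + frailty",
           compliance = stats::setNames(compliance, id)),
         masks = NULL),
    class = "cea_cohort")
}

rgamma_safe <- function(n, shape, scale) pmax(stats::rgamma(n, shape = shape, scale = scale), 0.1)

# Map a latent health score to EQ-5D dimension levels: each dimension adds
# independent noise, then cutpoints assign levels (higher score = better).
profile_from_score <- function(score, instrument) {
  out <- purrr::map(eq5d_dimensions(), function(d) {
    x <- score + rnorm(length(score), 0, 0.12)
    lvl3 <- cut(x, c(-Inf, 0.35, 0.72, Inf), labels = FALSE)
    lvl3 <- 4L - lvl3                               # 1 best .. 3 worst
    lvl5 <- cut(x, c(-Inf, 0.25, 0.45, 0.62, 0.78, Inf), labels = FALSE)
    lvl5 <- 6L - lvl5                               # 1 best .. 5 worst
    ifelse(instrument == "EQ5D5L", lvl5, lvl3)
  })
  names(out) <- eq5d_dimensions()
  tibble::as_tibble(out)
}

#' Apply missingness to a fully observed cohort
#'
#' Removes post-baseline EQ-5D responses at the configured rate (MCAR or MAR
#' given baseline age), nulls baseline height/weight/smoking/utility-visit
#' cells at their own rates, and removes post-baseline risk-factor values.
#' The removed cells are recorded in `masks` so tests can recover exactly
#' which cells were deleted. Under MAR the intercept is calibrated so the
#' realized marginal rate still matches the configured rate.
#'
#' @param cohort A `cea_cohort` from [generate_cohort()].
#' @param config The [cohort_config()] holding the missingness settings.
#' @return The cohort with nulled cells and a `masks` element (tibbles of
#'   removed utility visits, baseline fields, and risk-factor cells).
#' @export
apply_missingness <- function(cohort, config) {
  stop_if_not_cohort(cohort)
  rate <- config$missing_utility_rate
  if (rate < 0 || rate >= 1) abort("missing rate must lie in [0, 1)")
  withr::with_seed(child_seed(config$seed, 101), {
    apply_missingness_impl(cohort, config)
  })
}

apply_missingness_impl <- function(cohort, config) {
  rate <- config$missing_utility_rate
  ut <- cohort$utilities
  post <- ut$visit_time > 0
  if (rate > 0 && any(post)) {
    if (config$missingness_mechanism == "MAR") {
      age <- cohort$patients$age[match(ut$patient_id, cohort$patients$patient_id)]
      z <- 0.06 * (age[post] - mean(age))
      # calibrate the intercept so the marginal removal rate equals `rate`
      a <- uniroot(function(a) mean(plogis(a + z)) - rate, c(-20, 20))$root
      p <- plogis(a + z)
    } else {
      p <- rate
    }
    rm_u <- post & (runif(nrow(ut)) < ifelse(post, replace_in(post, p), 0))
  } else {
    rm_u <- rep(FALSE, nrow(ut))
  }
  dims <- eq5d_dimensions()
  ut[rm_u, dims] <- NA_integer_

  # baseline visit-0 utility responses
  r0 <- config$baseline_missing_rates[["utility"]]
  base_rows <- which(ut$visit_time == 0)
  rm_b <- base_rows[runif(length(base_rows)) < r0]
  ut[rm_b, dims] <- NA_integer_

  pat <- cohort$patients
  rm_field <- purrr::map(c("height", "weight", "smoking"), function(f) {
    r <- config$baseline_missing_rates[[f]]
    sel <- runif(nrow(pat)) < r
    pat[[f]][sel] <<- if (is.character(pat[[f]])) NA_character_ else NA_real_
    tibble::tibble(patient_id = pat$patient_id[sel], field = f)
  })

  rf <- cohort$risk_factors
  rm_rf <- rf$visit_time > 0 &
    runif(nrow(rf)) < config$risk_factor_missing_rate
  rf$value[rm_rf] <- NA_real_

  cohort$utilities <- ut
  cohort$patients <- pat
  cohort$risk_factors <- rf
  cohort$masks <- list(
    utilities = tibble::tibble(patient_id = ut$patient_id,
                               visit_time = ut$visit_time,
                               removed = rm_u | seq_len(nrow(ut)) %in% rm_b),
    baseline_fields = dplyr::bind_rows(rm_field),
    risk_factors = tibble::tibble(patient_id = rf$patient_id,
                                  visit_time = rf$visit_time,
                                  factor = rf$factor, removed = rm_rf))
  cohort
}

# expand a scalar-or-subset probability onto the full logical index
replace_in <- function(idx, p) {
  out <- numeric(length(idx))
  out[idx] <- p
  out
}

#' @export
print.cea_cohort <- function(x, ...) {
  cat("<cea_cohort> ", nrow(x$patients), " patients (",
      sum(x$patients$arm == "active"), " active / ",
      sum(x$patients$arm == "control"), " control)\n", sep = "")
  cat("  utilities: ", nrow(x$utilities), " visit records; events: ",
      nrow(x$events), "; missingness ",
      if (is.null(x$masks)) "not yet applied" else "applied", "\n", sep = "")
  invisible(x)
}
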