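# Handcrafted fixtures built in code: a minimal cohort constructor, a toy
# value set, and simple risk-equation builders.

empty_utilities <- function() {
  tibble::tibble(patient_id = character(), visit_time = numeric(),
                 instrument = character(), mobility = integer(),
                 self_care = integer(), usual_activities = integer(),
                 pain_discomfort = integer(), anxiety_depression = integer())
}

empty_resource_use <- function() {
  tibble::tibble(patient_id = character(), period_start = numeric(),
                 period_end = numeric(), inpatient_days = integer(),
                 outpatient_visits = integer(), conmed_units = integer(),
                 other_med_units = integer(), study_drug_doses = integer())
}

mini_cohort <- function(patients,
                        utilities = empty_utilities(),
                        resource_use = empty_resource_use(),
                        events = tibble::tibble(patient_id = character(),
                                                event = character(),
                                                time = numeric()),
                        risk_factors = tibble::tibble(
                          patient_id = character(), visit_time = numeric(),
                          factor = character(), value = numeric())) {
  structure(list(patients = tibble::as_tibble(patients),
                 utilities = tibble::as_tibble(utilities),
                 resource_use = tibble::as_tibble(resource_use),
                 events = tibble::as_tibble(events),
                 risk_factors = tibble::as_tibble(risk_factors),
                 ground_truth = NULL, masks = NULL),
            class = "cea_cohort")
}

# toy tariff: decrement 0.1 per level above 1, no interaction term
toy_value_set <- function() {
  dims <- eq5d_dimensions()
  trialcea:::validate_value_set(tibble::tibble(
    term = rep(dims, each = 2), level = rep(2:3, length(dims)),
    decrement = rep(c(0.1, 0.2), length(dims))))
}

# single-equation constructor (exponential unless told otherwise)
make_equation <- function(outcome, intercept, form = "exponential",
                          shape = NA, extra = NULL) {
  eq <- tibble::tibble(equation = outcome, form = form, shape = shape,
                       term = "intercept", estimate = intercept, ref = 0)
  if (!is.null(extra)) {
    extra$equation <- outcome
    extra$form <- form
    extra$shape <- shape
    eq <- dplyr::bind_rows(eq, extra)
  }
  validate_risk_equations(eq)
}

# profiles for direct engine tests: n identical patients
flat_profiles <- function(n, arm = "active", utility = 0.8, age = 65,
                          duration = 10, on_drug = FALSE,
                          compliance = 1, conmed_rate = 0) {
  tibble::tibble(patient_id = sprintf("S%05d", seq_len(n)), arm = arm,
                 age = age, duration = duration, female = 0, prior_cvd = 0,
                 followup_end = 3, utility = utility,
                 compliance = compliance, conmed_rate = conmed_rate,
                 on_drug = on_drug, hba1c = 8, sbp = 135, ldl = 2.3,
                 hdl = 1.1, bmi = 32, heart_rate = 75, egfr = 75)
}

zero_cost_table <- function() {
  trialcea::read_complication_table(
    system.file("extdata", "complication_table_us_synthetic.csv",
                package = "trialcea")) |>
    dplyr::mutate(cost_event = 0, cost_ongoing = 0,
                  utility_event = 0, utility_ongoing = 0)
}

free_costing <- function(rate = 0) {
  cc <- costing_config("US")
  cc$unit_costs[] <- 0
  cc$eqw_price_per_dose <- 0
  cc$standard_care_annual <- 0
  cc$background_annual <- 0
  cc$discount_rate <- rate
  cc
}
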