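## Annual-cycle patient-level extrapolation from end-of-trial profiles to
## death: competing complication/death risks, risk-factor trajectories,
## treatment-continuation rules, and discounted accrual of costs, life-years
## and QALYs.

#' Extrapolation (microsimulation) configuration
#'
#' @param horizon Maximum number of annual cycles simulated.
#' @param age_cap Simulation stops for a patient once age reaches this cap.
#' @param discount_cost,discount_effect Annual discount rates for costs and
#'   for life-years/QALYs.
#' @param trajectory_mode Risk-factor trajectories beyond the trial:
#'   `"constant"` (base case: all factors other than age, diabetes duration
#'   and event history held at end-of-trial levels), `"linear-drift"`
#'   (factors drift by `drift` per year), or `"user-table"` (per-year values
#'   supplied in `user_table`).
#' @param drift Named per-year additive drift for `"linear-drift"`.
#' @param user_table For `"user-table"`: tibble `factor`, `year`, `value`
#'   giving absolute factor values by extrapolation year.
#' @param scenario Treatment-continuation scenario: `"base"` (active-arm
#'   patients stay on study drug at trial-end compliance until death or
#'   renal failure), `"scenario1"` (everyone off study drug from
#'   extrapolation year 0), `"scenario2"` (on-drug patients stop with a
#'   constant annual probability during the first `scenario2_window` years,
#'   then remain on).
#' @param scenario2_stop_rate Annual stop probability for scenario 2
#'   (placeholder default 0.05; set it to the discontinuation rate observed
#'   after the first trial year when known).
#' @param scenario2_window Years over which scenario-2 stopping operates.
#' @param n_draws Number of risk-equation coefficient draws.
#' @param seed Integer seed; the event uniforms are drawn from a stream
#'   that depends only on this seed, giving common random numbers across
#'   arms, scenarios and coefficient draws.
#' @param utility_floor Utility is not decremented below this floor.
#' @param discount_from `"extrapolation_start"` (discount year 0 is the
#'   first post-trial year) or `"randomization"` (each patient's discount
#'   clock continues from randomization, offset by their follow-up length).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(horizon = 60, age_cap = 100,
                       discount_cost = 0.03, discount_effect = 0.03,
                       trajectory_mode = c("constant", "linear-drift",
                                           "user-table"),
                       drift = NULL, user_table = NULL,
                       scenario = c("base", "scenario1", "scenario2"),
                       scenario2_stop_rate = 0.05, scenario2_window = 10,
                       n_draws = 800, seed = 1, utility_floor = 0,
                       discount_from = c("extrapolation_start",
                                         "randomization")) {
  trajectory_mode <- match.arg(trajectory_mode)
  scenario <- match.arg(scenario)
  discount_from <- match.arg(discount_from)
  if (!is_count(horizon)) abort("`horizon` must be a positive integer")
  if (discount_cost < 0 || discount_effect < 0) abort("rates must be >= 0")
  if (scenario2_stop_rate < 0 || scenario2_stop_rate > 1) {
    abort("`scenario2_stop_rate` must lie in [0, 1]")
  }
  if (trajectory_mode == "linear-drift" && is.null(drift)) {
    abort("`linear-drift` mode needs a named `drift` vector")
  }
  if (trajectory_mode == "user-table" && is.null(user_table)) {
    abort("`user-table` mode needs `user_table`")
  }
  structure(list(horizon = as.integer(horizon), age_cap = age_cap,
                 discount_cost = discount_cost,
                 discount_effect = discount_effect,
                 trajectory_mode = trajectory_mode, drift = drift,
                 user_table = user_table, scenario = scenario,
                 scenario2_stop_rate = scenario2_stop_rate,
                 scenario2_window = scenario2_window,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 utility_floor = utility_floor,
                 discount_from = discount_from),
            class = "sim_config")
}

#' Read / load per-complication utility decrements and costs
#'
#' Schema: `complication`, `cost_event` and `cost_ongoing` (event-year and
#' subsequent-year costs), `utility_event` and `utility_ongoing`
#' (decrements, >= 0). The packaged tables are synthetic placeholders.
#'
#' @param path CSV file path.
#' @param country `"US"` or `"UK"` for the packaged synthetic table.
#' @return A tibble of class `complication_table`.
#' @export
read_complication_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("complication", "cost_event", "cost_ongoing",
                  "utility_event", "utility_ongoing") %in% names(x)))
  if (any(x$cost_event < 0 | x$cost_ongoing < 0 |
            x$utility_event < 0 | x$utility_ongoing < 0)) {
    abort("complication costs and decrements must be >= 0")
  }
  bad <- setdiff(x$complication, complication_registry())
  if (length(bad)) abort(paste0("unknown complication(s): ",
                                paste(bad, collapse = ", ")))
  structure(tibble::as_tibble(x),
            class = c("complication_table", class(x)))
}

#' @rdname read_complication_table
#' @export
default_complication_table <- function(country = c("US", "UK")) {
  country <- match.arg(country)
  f <- sprintf("complication_table_%s_synthetic.csv", tolower(country))
  read_complication_table(system.file("extdata", f, package = "trialcea",
                                      mustWork = TRUE))
}

#' End-of-trial patient profiles for extrapolation
#'
#' Assembles one row per patient at their trial exit: age and diabetes
#' duration advanced by individual follow-up, risk-factor values at the
#' last visit (from the imputation-averaged table), first-event history
#' flags from within-trial events, entry utility (last valued utility,
#' averaged across imputations when several are supplied), last-year
#' study-drug compliance, and concomitant-medication rate.
#'
#' @param cohort A `cea_cohort`.
#' @param risk_factors A complete risk-factor table (e.g. from
#'   [average_risk_factor_imputations()]); defaults to the cohort's own
#'   (requires it complete).
#' @param utility_tables List of completed utility tibbles (e.g.
#'   `imputations$utilities`); defaults to the cohort's valued utilities.
#' @return A tibble of class `eot_profiles`.
#' @export
end_of_trial_profiles <- function(cohort, risk_factors = NULL,
                                  utility_tables = NULL) {
  stop_if_not_cohort(cohort)
  pat <- cohort$patients
  rf <- risk_factors %||% cohort$risk_factors
  if (anyNA(rf$value)) abort("risk-factor table has missing values")
  last_rf <- dplyr::slice_max(dplyr::group_by(rf, .data$patient_id,
                                              .data$factor),
                              .data$visit_time, n = 1, with_ties = FALSE)
  wide_rf <- tidyr::pivot_wider(dplyr::ungroup(last_rf),
                                id_cols = "patient_id",
                                names_from = "factor",
                                values_from = "value")

  uts <- utility_tables %||% list(cohort$utilities)
  u_end <- purrr::map(uts, function(ut) {
    if (anyNA(ut$utility)) abort("utility table has missing values")
    last <- dplyr::slice_max(dplyr::group_by(ut, .data$patient_id),
                             .data$visit_time, n = 1, with_ties = FALSE)
    last <- dplyr::ungroup(last)
    last$utility[match(pat$patient_id, last$patient_id)]
  })
  u0 <- Reduce(`+`, u_end) / length(u_end)

  ev <- cohort$events
  hist <- purrr::map(complication_registry(), function(e) {
    pat$patient_id %in% ev$patient_id[ev$event == e]
  })
  names(hist) <- paste0("hist_", complication_registry())

  ru <- cohort$resource_use
  last_ru <- dplyr::slice_max(dplyr::group_by(ru, .data$patient_id),
                              .data$period_start, n = 1, with_ties = FALSE)
  last_ru <- dplyr::ungroup(last_ru)
  len <- pmax(last_ru$period_end - last_ru$period_start, 1e-6)
  compliance <- pmin(last_ru$study_drug_doses / (52.18 * len), 1)
  conmed_rate <- last_ru$conmed_units / len
  i <- match(pat$patient_id, last_ru$patient_id)

  out <- dplyr::bind_cols(
    tibble::tibble(
      patient_id = pat$patient_id, arm = pat$arm,
      country_setting = pat$country_setting,
      alive_at_exit = is.na(pat$death_time),
      age = pat$age + pat$followup_end,
      duration = pat$diabetes_duration + pat$followup_end,
      female = as.numeric(pat$sex == "female"),
      prior_cvd = as.numeric(pat$prior_cvd),
      followup_end = pat$followup_end,
      utility = u0,
      compliance = dplyr::coalesce(compliance[i], 0),
      conmed_rate = dplyr::coalesce(conmed_rate[i], 0),
      on_drug = pat$arm == "active"),
    wide_rf[match(pat$patient_id, wide_rf$patient_id),
            setdiff(names(wide_rf), "patient_id")],
    tibble::as_tibble(hist))
  structure(out[out$alive_at_exit, , drop = FALSE],
            class = c("eot_profiles", class(out)))
}

#' Advance a profile by one or more annual cycles
#'
#' Age and diabetes duration increase by one year per cycle; event-history
#' flags are updated by the simulation trace, not here. Other risk factors
#' are held constant in the base case, drift linearly in `"linear-drift"`
#' mode, or follow `user_table` values in `"user-table"` mode.
#'
#' @param profile A profile tibble (rows = patients).
#' @param years Number of cycles to advance.
#' @param trajectory_mode,drift,user_table See [sim_config()].
#' @param year0 Extrapolation year index of the profile before the update
#'   (used by `"user-table"` mode).
#' @return The advanced profile.
#' @export
update_profile <- function(profile, years = 1,
                           trajectory_mode = "constant", drift = NULL,
                           user_table = NULL, year0 = 0) {
  if (!trajectory_mode %in% c("constant", "linear-drift", "user-table")) {
    abort(paste0("unknown trajectory mode: ", trajectory_mode))
  }
  profile$age <- profile$age + years
  profile$duration <- profile$duration + years
  if (trajectory_mode == "linear-drift") {
    for (f in names(drift)) {
      if (!is.null(profile[[f]])) {
        profile[[f]] <- profile[[f]] + drift[[f]] * years
      }
    }
  } else if (trajectory_mode == "user-table") {
    for (f in unique(user_table$factor)) {
      sub <- user_table[user_table$factor == f, ]
      v <- sub$value[match(year0 + years, sub$year)]
      if (!is.null(profile[[f]]) && !anyNA(v)) profile[[f]] <- v
    }
  }
  profile
}

#' Treatment-continuation rule
#'
#' Decides who remains on study drug next year under the configured
#' discontinuation scenario. Base case: active-arm patients stay on at
#' trial-end compliance until death or renal failure (immediately on its
#' development), then accrue the same therapy cost as standard care.
#' Scenario 1 takes everyone off study drug from extrapolation year 0.
#' Scenario 2 stops each on-drug patient with probability
#' `scenario2_stop_rate` per year during the first `scenario2_window`
#' years.
#'
#' @param state Tibble with logical columns `on_drug`, `alive`,
#'   `hist_renal_failure`.
#' @param scenario `"base"`, `"scenario1"` or `"scenario2"`.
#' @param config A [sim_config()].
#' @param year Extrapolation year index (0-based).
#' @param stop_draws Uniform draws (one per row) used by scenario 2.
#' @return Logical vector: on study drug next year.
#' @export
treatment_rule <- function(state, scenario, config, year = 0,
                           stop_draws = NULL) {
  if (!scenario %in% c("base", "scenario1", "scenario2")) {
    abort(paste0("unknown scenario: ", scenario))
  }
  on_next <- state$on_drug & state$alive & !state$hist_renal_failure
  if (scenario == "scenario1") return(rep(FALSE, nrow(state)))
  if (scenario == "scenario2" && year < config$scenario2_window) {
    if (is.null(stop_draws)) stop_draws <- runif(nrow(state))
    on_next <- on_next & !(stop_draws < config$scenario2_stop_rate)
  }
  on_next
}

## ---- engine ----------------------------------------------------------------

prep_equations <- function(equations) {
  eq <- validate_risk_equations(equations)
  nm <- unique(eq$equation)
  # death evaluated last within each cycle
  nm <- c(setdiff(nm, "death"), intersect("death", nm))
  purrr::map(stats::setNames(nm, nm), function(e) {
    sub <- eq[eq$equation == e, ]
    list(form = sub$form[1], shape = sub$shape[1],
         terms = sub$term, est = sub$estimate, ref = sub$ref)
  })
}

eval_probability <- function(spec, get_term, duration) {
  lp <- 0
  for (i in seq_along(spec$terms)) {
    if (spec$terms[i] == "intercept") {
      lp <- lp + spec$est[i]
    } else {
      lp <- lp + spec$est[i] * (get_term(spec$terms[i]) - spec$ref[i])
    }
  }
  switch(spec$form,
         logistic = plogis(lp),
         exponential = 1 - exp(-exp(lp)),
         weibull = {
           H1 <- exp(lp) * (duration + 1)^spec$shape
           H0 <- exp(lp) * duration^spec$shape
           pmin(pmax(1 - exp(-(H1 - H0)), 0), 1)
         },
         gompertz = {
           H1 <- exp(lp) / spec$shape * (exp(spec$shape * (duration + 1)) - 1)
           H0 <- exp(lp) / spec$shape * (exp(spec$shape * duration) - 1)
           pmin(pmax(1 - exp(-(H1 - H0)), 0), 1)
         })
}

# Vectorized annual-cycle simulation of one set of profiles under one
# coefficient set. The uniform stream is a function of config$seed only
# (drawn for all patients every year in fixed order), so runs with the same
# seed share event randomness across arms, scenarios and coefficient draws.
simulate_profiles <- function(profiles, equations, comp_table, costing,
                              config, trace = FALSE) {
  n <- nrow(profiles)
  if (n == 0) abort("empty cohort")
  if (config$horizon < 1) abort("`horizon` must be >= 1")
  specs <- prep_equations(equations)
  eq_names <- names(specs)
  comps_used <- setdiff(eq_names, "death")
  ct <- comp_table
  rf_names <- intersect(risk_factor_registry(), names(profiles))
  need <- setdiff(unlist(purrr::map(specs, "terms")),
                  c("intercept", "age", "duration", "on_drug",
                    paste0("hist_", complication_registry())))
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    abort(paste0("profiles incomplete: missing term(s) ",
                 paste(miss, collapse = ", ")))
  }

  age <- profiles$age
  duration <- profiles$duration
  rf <- as.list(profiles[rf_names])
  static <- as.list(profiles[intersect(c("female", "prior_cvd"),
                                       names(profiles))])
  hist <- matrix(FALSE, n, length(complication_registry()),
                 dimnames = list(NULL, paste0("hist_",
                                              complication_registry())))
  for (h in colnames(hist)) {
    if (!is.null(profiles[[h]])) hist[, h] <- as.logical(profiles[[h]])
  }
  alive <- rep(TRUE, n)
  on_drug <- profiles$on_drug
  if (config$scenario == "scenario1") on_drug <- rep(FALSE, n)
  utility0 <- profiles$utility
  compliance <- profiles$compliance %||% rep(1, n)
  conmed_rate <- profiles$conmed_rate %||% rep(0, n)

  offset <- if (config$discount_from == "randomization") {
    profiles$followup_end
  } else {
    rep(0, n)
  }
  drug_annual <- 52.18 * costing$eqw_price_per_dose * compliance
  conmed_annual <- conmed_rate * costing$unit_costs[["conmed_unit"]]

  zero <- numeric(n)
  acc <- list(cost_therapy = zero, cost_other = zero, ly = zero,
              qaly = zero, ly_undisc = zero, qaly_undisc = zero,
              cost_undisc = zero)
  floored <- 0L
  traces <- if (trace) vector("list", config$horizon)

  withr::with_seed(config$seed, {
    for (y in seq_len(config$horizon) - 1) {
      # fixed-order uniform draws for every patient keep the stream common
      U <- matrix(runif(n * length(eq_names)), n,
                  dimnames = list(NULL, eq_names))
      u_stop <- runif(n)
      at_risk <- alive & age < config$age_cap
      if (!any(at_risk)) break

      get_term <- function(term) {
        switch(term,
               age = age, duration = duration, on_drug = as.numeric(on_drug),
               if (term %in% colnames(hist)) as.numeric(hist[, term])
               else if (term %in% names(rf)) rf[[term]]
               else static[[term]])
      }
      new_ev <- matrix(FALSE, n, length(comps_used),
                       dimnames = list(NULL, comps_used))
      for (e in comps_used) {
        p <- eval_probability(specs[[e]], get_term, duration)
        new_ev[, e] <- at_risk & !hist[, paste0("hist_", e)] &
          (as.vector(U[, e]) < p)
      }
      died <- rep(FALSE, n)
      if ("death" %in% eq_names) {
        p <- eval_probability(specs[["death"]], get_term, duration)
        died <- at_risk & (as.vector(U[, "death"]) < p)
      }

      # accrual for patients alive at cycle start (death at end of cycle)
      renal_now <- if ("renal_failure" %in% comps_used) {
        as.vector(new_ev[, "renal_failure"])
      } else {
        rep(FALSE, n)
      }
      drug_now <- on_drug & !renal_now
      therapy <- ifelse(drug_now, drug_annual, costing$standard_care_annual) +
        conmed_annual
      if (length(comps_used)) {
        i_ev <- match(comps_used, ct$complication)
        ong <- hist[, paste0("hist_", comps_used), drop = FALSE]
        ev_cost <- drop(new_ev %*% ifelse(is.na(i_ev), 0,
                                          ct$cost_event[i_ev]))
        ong_cost <- drop(ong %*% ifelse(is.na(i_ev), 0,
                                        ct$cost_ongoing[i_ev]))
        dec <- drop(new_ev %*% ifelse(is.na(i_ev), 0,
                                      ct$utility_event[i_ev])) +
          drop(ong %*% ifelse(is.na(i_ev), 0, ct$utility_ongoing[i_ev]))
      } else {
        ev_cost <- ong_cost <- dec <- zero
      }
      other <- costing$background_annual + ev_cost + ong_cost
      util_y <- utility0 - dec
      fl <- at_risk & util_y < config$utility_floor
      floored <- floored + sum(fl)
      util_y <- pmax(util_y, config$utility_floor)

      dfc <- 1 / (1 + config$discount_cost)^(offset + y)
      dfe <- 1 / (1 + config$discount_effect)^(offset + y)
      live <- as.numeric(at_risk)
      acc$cost_therapy <- acc$cost_therapy + live * therapy * dfc
      acc$cost_other <- acc$cost_other + live * other * dfc
      acc$cost_undisc <- acc$cost_undisc + live * (therapy + other)
      acc$ly <- acc$ly + live * dfe
      acc$qaly <- acc$qaly + live * util_y * dfe
      acc$ly_undisc <- acc$ly_undisc + live
      acc$qaly_undisc <- acc$qaly_undisc + live * util_y

      if (trace) {
        traces[[y + 1]] <- tibble::tibble(
          year = y, patient = seq_len(n), age = age,
          duration = duration, alive_start = at_risk,
          events = if (length(comps_used)) {
            apply(new_ev, 1, function(r) paste(comps_used[r],
                                               collapse = ";"))
          } else {
            character(n)
          },
          death = died, on_drug = drug_now & at_risk,
          utility = ifelse(at_risk, util_y, NA_real_),
          cost_therapy = live * therapy, cost_other = live * other,
          disc_qaly = live * util_y * dfe, disc_cost = live *
            (therapy + other) * dfc,
          alive_end = at_risk & !died)
      }

      # state update
      for (e in comps_used) {
        hist[, paste0("hist_", e)] <- hist[, paste0("hist_", e)] | new_ev[, e]
      }
      alive <- alive & !died
      st <- tibble::tibble(on_drug = on_drug, alive = alive,
                           hist_renal_failure = as.vector(hist[, "hist_renal_failure"]))
      on_drug <- treatment_rule(st, config$scenario, config, year = y,
                                stop_draws = u_stop)
      age <- age + 1
      duration <- duration + 1
      if (config$trajectory_mode == "linear-drift") {
        for (f in names(config$drift)) {
          if (f %in% names(rf)) rf[[f]] <- rf[[f]] + config$drift[[f]]
        }
      } else if (config$trajectory_mode == "user-table") {
        utb <- config$user_table
        for (f in unique(utb$factor)) {
          sub <- utb[utb$factor == f, ]
          v <- sub$value[match(y + 1, sub$year)]
          if (f %in% names(rf) && length(v) == 1 && !is.na(v)) {
            rf[[f]] <- rep(v, n)
          }
        }
      }
    }
  })

  totals <- tibble::tibble(
    patient_id = profiles$patient_id %||% as.character(seq_len(n)),
    arm = profiles$arm %||% NA_character_,
    cost_therapy = acc$cost_therapy, cost_other = acc$cost_other,
    cost_total = acc$cost_therapy + acc$cost_other,
    life_years = acc$ly, qalys = acc$qaly,
    life_years_undisc = acc$ly_undisc, qalys_undisc = acc$qaly_undisc,
    cost_total_undisc = acc$cost_undisc)
  attr(totals, "n_floored") <- floored
  if (trace) {
    list(totals = totals, trace = dplyr::bind_rows(traces))
  } else {
    totals
  }
}

#' Simulate one patient and return the yearly trace
#'
#' Runs the annual-cycle engine for a single end-of-trial profile and
#' returns the year-by-year trace (events, therapy status, utility, costs,
#' discounted contributions) alongside discounted totals.
#'
#' @param profile One-row profile tibble (see [end_of_trial_profiles()]).
#' @param equations A `risk_equations` table.
#' @param comp_table A `complication_table`.
#' @param costing A [costing_config()].
#' @param config A [sim_config()].
#' @return List with elements `trace` (tibble of `YearTrace` rows) and
#'   `totals` (one-row tibble).
#' @export
simulate_patient <- function(profile, equations, comp_table, costing,
                             config) {
  if (nrow(profile) != 1) abort("`profile` must have exactly one row")
  out <- simulate_profiles(profile, equations, comp_table, costing, config,
                           trace = TRUE)
  out$trace <- out$trace[out$trace$alive_start, ]
  out
}

#' Simulate a cohort across coefficient draws
#'
#' For each risk-equation coefficient set, simulates every patient arm by
#' arm under common random numbers (the event uniform stream depends only
#' on the seed, not on the arm or the draw) and returns per-draw, per-arm
#' mean discounted outcomes. Draw 0 is the point estimate.
#'
#' @param profiles An `eot_profiles` tibble (column `arm` present).
#' @param draws A list of coefficient sets from [draw_coefficients()], or a
#'   single `risk_equations` table (then `config$n_draws` draws are taken
#'   with `covariance`).
#' @param comp_table A `complication_table`.
#' @param costing A [costing_config()].
#' @param config A [sim_config()].
#' @param covariance Optional covariance passed to [draw_coefficients()]
#'   when `draws` is a single table.
#' @return Tibble keyed by (`draw`, `arm`): `n`, mean `cost_therapy`,
#'   `cost_other`, `cost_total`, `life_years`, `qalys` (all discounted) and
#'   undiscounted life-years/QALYs.
#' @export
simulate_cohort <- function(profiles, draws, comp_table, costing, config,
                            covariance = NULL) {
  if (nrow(profiles) == 0) abort("empty cohort")
  if (inherits(draws, "risk_equations") || is.data.frame(draws)) {
    draws <- draw_coefficients(draws, covariance, config$n_draws,
                               seed = child_seed(config$seed, 7))
  }
  arms <- split(seq_len(nrow(profiles)), profiles$arm)
  purrr::map_dfr(seq_along(draws) - 1, function(d) {
    eq <- draws[[d + 1]]
    purrr::map_dfr(names(arms), function(a) {
      sub <- profiles[arms[[a]], , drop = FALSE]
      tot <- simulate_profiles(sub, eq, comp_table, costing, config)
      tibble::tibble(draw = d, arm = a, n = nrow(sub),
                     cost_therapy = mean(tot$cost_therapy),
                     cost_other = mean(tot$cost_other),
                     cost_total = mean(tot$cost_total),
                     life_years = mean(tot$life_years),
                     qalys = mean(tot$qalys),
                     life_years_undisc = mean(tot$life_years_undisc),
                     qalys_undisc = mean(tot$qalys_undisc))
    })
  })
}
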