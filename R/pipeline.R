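## End-to-end analysis: configuration, the full pipeline run, scenario
## re-runs, and broom-style accessors for the fitted result.

#' Full analysis configuration
#'
#' One configuration object drives every pipeline stage. Defaults match the
#' base case: 28 imputations, 800 bootstrap replicates and coefficient
#' draws, country-specific discounting (3% US / 3.5% UK), and the base
#' treatment-continuation scenario.
#'
#' @param country `"US"` or `"UK"`; sets the default value set, costing and
#'   discount rates.
#' @param m Number of imputed datasets.
#' @param B Bootstrap replicates per imputation.
#' @param n_draws Risk-equation coefficient draws for the post-trial period.
#' @param seed Master seed; stage seeds are derived from it.
#' @param costing A [costing_config()].
#' @param value_set,crosswalk Valuation inputs.
#' @param equations Risk equations for the extrapolation.
#' @param coef_covariance Covariance for [draw_coefficients()]; defaults to
#'   diagonal intercept uncertainty via [default_coef_covariance()]. Set
#'   `NULL` to disable parameter uncertainty.
#' @param comp_table Complication decrement/cost table.
#' @param sim A [sim_config()]; its discount rates default to the costing
#'   rate and its `n_draws`/`seed` are aligned with this config.
#' @param imputation An [imputation_config()]; `m`/`seed` aligned likewise.
#' @param qaly_tail Censoring-tail rule for [auc_qalys()].
#' @return A list of class `cea_config`.
#' @export
cea_config <- function(country = c("US", "UK"), m = 28, B = 800,
                       n_draws = 800, seed = 1,
                       costing = costing_config(country),
                       value_set = default_value_set(country),
                       crosswalk = default_crosswalk(),
                       equations = default_risk_equations(),
                       coef_covariance = default_coef_covariance(equations),
                       comp_table = default_complication_table(country),
                       sim = NULL, imputation = NULL,
                       qaly_tail = "carry_forward") {
  country <- match.arg(country)
  sim <- sim %||% sim_config(discount_cost = costing$discount_rate,
                             discount_effect = costing$discount_rate,
                             n_draws = n_draws, seed = seed)
  sim$n_draws <- as.integer(n_draws)
  sim$seed <- child_seed(seed, 3)
  imputation <- imputation %||% imputation_config(m = m, seed = seed)
  imputation$m <- as.integer(m)
  imputation$seed <- child_seed(seed, 2)
  structure(list(country = country, m = as.integer(m), B = as.integer(B),
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 costing = costing, value_set = value_set,
                 crosswalk = crosswalk, equations = equations,
                 coef_covariance = coef_covariance,
                 comp_table = comp_table, sim = sim,
                 imputation = imputation, qaly_tail = qaly_tail),
            class = "cea_config")
}

#' Run the full cost-utility analysis
#'
#' Executes the pipeline on a cohort: EQ-5D valuation, deterministic
#' baseline imputation, chained-equation multiple imputation of
#' post-baseline utilities and risk factors, per-imputation within-trial
#' QALYs and costs, risk-factor averaging into end-of-trial profiles,
#' lifetime extrapolation across coefficient draws, and the bootstrap ×
#' imputation uncertainty machinery.
#'
#' @param cohort A `cea_cohort` (with or without missingness applied).
#' @param config A [cea_config()].
#' @return An object of class `cea_result` with elements `point` (tidy
#'   point estimates), `replicates` (the lifetime replicate table), `ci`,
#'   `ceac`, `table1`, `post_draws`, `within_point`, `n`, `config` and
#'   `manifest`.
#' @export
run_cea <- function(cohort, config = cea_config()) {
  stop_if_not_cohort(cohort)
  if (!inherits(config, "cea_config")) abort("`config` must be a `cea_config`")

  dataset <- add_utility_values(cohort, config$value_set, config$crosswalk)
  dataset <- impute_baseline(dataset)
  imps <- impute_chained(dataset, config$imputation)
  per_patient <- within_trial_results(dataset, imps, config$costing,
                                      tail = config$qaly_tail)

  # within-trial point estimates: adjusted QALY means, unadjusted costs,
  # averaged over imputations
  wt_point <- within_trial_point(per_patient)

  rf_avg <- average_risk_factor_imputations(imps)
  profiles <- end_of_trial_profiles(dataset, risk_factors = rf_avg,
                                    utility_tables = imps$utilities)
  post <- simulate_cohort(profiles, config$equations, config$comp_table,
                          config$costing, config$sim,
                          covariance = config$coef_covariance)
  post_inc <- post_increments(post)

  within_reps <- bootstrap_within_trial(per_patient, B = config$B,
                                        seed = child_seed(config$seed, 4))
  reps <- combine_periods(within_reps, post_inc,
                          pairing = if (nrow(post_inc[post_inc$draw > 0, ]) <
                                          config$B) "shared" else "by_replicate")

  point0 <- post_inc[post_inc$draw == 0, ]
  dcost <- wt_point$dcost + point0$dcost
  dqaly <- wt_point$dqaly + point0$dqaly
  dly <- wt_point$dly + point0$dly
  pt <- icer(dcost, dqaly)
  ci <- tibble::tibble(
    quantity = c("lifetime_dcost", "lifetime_dqaly", "lifetime_dly", "icer"),
    lower = c(percentile_ci(reps$lifetime_dcost)[1],
              percentile_ci(reps$lifetime_dqaly)[1],
              percentile_ci(reps$lifetime_dly)[1],
              icer_ci(reps)[1]),
    upper = c(percentile_ci(reps$lifetime_dcost)[2],
              percentile_ci(reps$lifetime_dqaly)[2],
              percentile_ci(reps$lifetime_dly)[2],
              icer_ci(reps)[2]))
  cc <- ceac(reps)

  tab1 <- lifetime_table(table1_components(wt_point, post))

  res <- list(
    point = tibble::tibble(
      dcost = dcost, dqaly = dqaly, dly = dly, icer = pt$icer,
      quadrant = pt$quadrant,
      within_dcost = wt_point$dcost, within_dqaly = wt_point$dqaly,
      post_dcost = point0$dcost, post_dqaly = point0$dqaly),
    replicates = reps, ci = ci, ceac = cc, table1 = tab1,
    post_draws = post, within_point = wt_point,
    per_patient_point = per_patient,
    n = nrow(cohort$patients),
    n_arms = table(cohort$patients$arm),
    config = config,
    manifest = run_manifest(config, n = nrow(cohort$patients)))
  structure(res, class = "cea_result")
}

within_trial_point <- function(per_patient) {
  by_imp <- purrr::map_dfr(split(per_patient, per_patient$imputation),
                           function(d) {
    adj <- baseline_adjust(d)
    act <- d$arm == "active"
    tibble::tibble(
      dqaly = adj$difference, qaly_active = adj$mean_active,
      qaly_control = adj$mean_control,
      dly = mean(d$life_years[act]) - mean(d$life_years[!act]),
      ly_active = mean(d$life_years[act]),
      ly_control = mean(d$life_years[!act]),
      dcost = mean(d$total_cost[act]) - mean(d$total_cost[!act]),
      dcost_therapy = mean(d$therapy_cost[act]) - mean(d$therapy_cost[!act]),
      dcost_other = mean(d$other_cost[act]) - mean(d$other_cost[!act]),
      therapy_active = mean(d$therapy_cost[act]),
      therapy_control = mean(d$therapy_cost[!act]),
      other_active = mean(d$other_cost[act]),
      other_control = mean(d$other_cost[!act]))
  })
  dplyr::summarise(by_imp, dplyr::across(dplyr::everything(), mean))
}

post_increments <- function(post) {
  wide <- tidyr::pivot_wider(post, id_cols = "draw", names_from = "arm",
                             values_from = c("cost_total", "cost_therapy",
                                             "cost_other", "qalys",
                                             "life_years"))
  tibble::tibble(
    draw = wide$draw,
    dcost = wide$cost_total_active - wide$cost_total_control,
    dcost_therapy = wide$cost_therapy_active - wide$cost_therapy_control,
    dcost_other = wide$cost_other_active - wide$cost_other_control,
    dqaly = wide$qalys_active - wide$qalys_control,
    dly = wide$life_years_active - wide$life_years_control)
}

table1_components <- function(wt, post) {
  p0 <- post[post$draw == 0, ]
  pa <- p0[p0$arm == "active", ]
  pc <- p0[p0$arm == "control", ]
  tibble::tribble(
    ~quantity, ~period, ~arm, ~value,
    "therapy_cost", "within", "active", wt$therapy_active,
    "therapy_cost", "within", "control", wt$therapy_control,
    "other_cost", "within", "active", wt$other_active,
    "other_cost", "within", "control", wt$other_control,
    "qalys", "within", "active", wt$qaly_active,
    "qalys", "within", "control", wt$qaly_control,
    "life_years", "within", "active", wt$ly_active,
    "life_years", "within", "control", wt$ly_control,
    "therapy_cost", "post", "active", pa$cost_therapy,
    "therapy_cost", "post", "control", pc$cost_therapy,
    "other_cost", "post", "active", pa$cost_other,
    "other_cost", "post", "control", pc$cost_other,
    "qalys", "post", "active", pa$qalys,
    "qalys", "post", "control", pc$qalys,
    "life_years", "post", "active", pa$life_years,
    "life_years", "post", "control", pc$life_years)
}

# percentile bounds on the ICER itself: valid as ratio percentiles only
# when every replicate lies in the NE quadrant; otherwise NA bounds
icer_ci <- function(reps) {
  if (all(reps$lifetime_dqaly > 0 & reps$lifetime_dcost > 0)) {
    percentile_ci(reps$lifetime_dcost / reps$lifetime_dqaly)
  } else {
    c(NA_real_, NA_real_)
  }
}

#' Re-run the analysis under sensitivity and subgroup scenarios
#'
#' Each scenario re-runs the pipeline with its configuration delta:
#' price-discount scenarios rescale the study-drug price only;
#' discontinuation scenarios switch the extrapolation treatment rule;
#' discount-rate variants change both discount rates; subgroup scenarios
#' filter the cohort before analysis. An empty subgroup is reported (NA
#' row), not fatal.
#'
#' @param cohort A `cea_cohort`.
#' @param config Base [cea_config()].
#' @param scenarios Named list from [scenario_grid()].
#' @return Tibble of per-scenario results (one [glance()] row each, with
#'   `scenario` and subgroup `n`).
#' @export
run_scenarios <- function(cohort, config = cea_config(),
                          scenarios = scenario_grid()) {
  purrr::map_dfr(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    co <- cohort
    cf <- config
    if (sc$type == "price_discount") {
      cf$costing$eqw_price_per_dose <-
        cf$costing$eqw_price_per_dose * (1 - sc$fraction)
    } else if (sc$type == "discontinuation") {
      cf$sim$scenario <- sc$scenario
    } else if (sc$type == "discount_rate") {
      cf$costing$discount_rate <- sc$rate
      cf$sim$discount_cost <- sc$rate
      cf$sim$discount_effect <- sc$rate
    } else if (sc$type == "subgroup") {
      keep <- sc$predicate(cohort$patients)
      ids <- cohort$patients$patient_id[keep]
      if (length(ids) == 0 ||
          length(unique(cohort$patients$arm[keep])) < 2) {
        warn(paste0("scenario ", nm,
                    ": empty or single-arm subgroup; skipped"))
        return(tibble::tibble(scenario = nm, n = length(ids)))
      }
      co <- filter_cohort(cohort, ids)
    } else {
      abort(paste0("unknown scenario type: ", sc$type))
    }
    res <- run_cea(co, cf)
    dplyr::bind_cols(tibble::tibble(scenario = nm), glance(res))
  })
}

filter_cohort <- function(cohort, ids) {
  for (t in c("patients", "utilities", "resource_use", "events",
              "risk_factors")) {
    cohort[[t]] <- cohort[[t]][cohort[[t]]$patient_id %in% ids, ]
  }
  cohort
}

## ---- accessors -------------------------------------------------------------

#' @export
print.cea_result <- function(x, ...) {
  p <- x$point
  cat("<cea_result>  n =", x$n, " (m =", x$config$m, ", B =", x$config$B,
      ", draws =", x$config$n_draws, ")\n")
  cat(sprintf("  incremental cost:  %12.2f (%.2f to %.2f)\n", p$dcost,
              x$ci$lower[1], x$ci$upper[1]))
  cat(sprintf("  incremental QALYs: %12.4f (%.4f to %.4f)\n", p$dqaly,
              x$ci$lower[2], x$ci$upper[2]))
  cat(sprintf("  ICER: %s per QALY [%s]\n",
              ifelse(is.na(p$icer), "undefined", format(round(p$icer, 0),
                                                        big.mark = ",")),
              p$quadrant))
  invisible(x)
}

#' Tidy and one-row summaries of a fitted analysis
#'
#' `tidy()` returns the estimates (incremental cost, QALYs, life-years,
#' ICER) with percentile interval bounds; `glance()` returns a one-row
#' summary including the design sizes.
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cea_result <- function(x, ...) {
  p <- x$point
  tibble::tibble(
    term = c("lifetime_dcost", "lifetime_dqaly", "lifetime_dly", "icer"),
    estimate = c(p$dcost, p$dqaly, p$dly, p$icer),
    conf.low = x$ci$lower, conf.high = x$ci$upper)
}

#' @rdname tidy.cea_result
#' @export
glance.cea_result <- function(x, ...) {
  p <- x$point
  tibble::tibble(n = x$n, m = x$config$m, B = x$config$B,
                 n_draws = x$config$n_draws,
                 dcost = p$dcost, dqaly = p$dqaly, dly = p$dly,
                 icer = p$icer, quadrant = p$quadrant,
                 dcost_low = x$ci$lower[1], dcost_high = x$ci$upper[1],
                 dqaly_low = x$ci$lower[2], dqaly_high = x$ci$upper[2])
}
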