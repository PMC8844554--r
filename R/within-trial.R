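## Within-trial economics: AUC QALYs with baseline adjustment, resource-use
## costing split into therapy vs other costs, and annual discounting.

#' Costing configuration
#'
#' Unit costs, study-drug pricing and the annual discount rate for one
#' country setting. Defaults follow the analysis conventions: reference year
#' 2017 (US, costs in USD) or 2016 (UK, GBP); discounting at 3% per annum in
#' the US and 3.5% in the UK; and a US study-drug price of USD 119.70 per
#' weekly dose, i.e. the wholesale acquisition price after a 23.1% discount
#' (the mean Medicaid discount on brand-name medications). The UK price is
#' GBP 18.94 per dose with no wholesale discount. Unit costs for resource
#' items are editable placeholders with realistic magnitudes.
#'
#' @param country `"US"` or `"UK"`.
#' @param unit_costs Named vector covering `inpatient_day`,
#'   `outpatient_visit`, `conmed_unit` (concomitant diabetes medication,
#'   per defined daily unit) and `other_med_unit`.
#' @param eqw_price_per_dose Study-drug price per weekly dose (after any
#'   wholesale discount).
#' @param wholesale_discount Fraction already taken off the wholesale
#'   acquisition price in `eqw_price_per_dose`.
#' @param discount_rate Annual discount rate for costs and effects.
#' @param reference_year Cost reference year (metadata).
#' @param standard_care_annual Annual therapy cost accrued by patients not
#'   on study drug during extrapolation.
#' @param background_annual Annual non-complication healthcare cost during
#'   extrapolation.
#' @return A list of class `costing_config`.
#' @export
#' @examples
#' us <- costing_config("US")
#' eqw_wholesale_price(us)  # inverts the 23.1% discount: about 155.66
costing_config <- function(country = c("US", "UK"),
                           unit_costs = NULL,
                           eqw_price_per_dose = NULL,
                           wholesale_discount = NULL,
                           discount_rate = NULL,
                           reference_year = NULL,
                           standard_care_annual = NULL,
                           background_annual = NULL) {
  country <- match.arg(country)
  us <- country == "US"
  unit_costs <- unit_costs %||% if (us) {
    c(inpatient_day = 2400, outpatient_visit = 150,
      conmed_unit = 0.9, other_med_unit = 0.5)
  } else {
    c(inpatient_day = 586, outpatient_visit = 49,
      conmed_unit = 0.12, other_med_unit = 0.08)
  }
  eqw_price_per_dose <- eqw_price_per_dose %||% if (us) 119.70 else 18.94
  wholesale_discount <- wholesale_discount %||% if (us) 0.231 else 0
  discount_rate <- discount_rate %||% if (us) 0.03 else 0.035
  reference_year <- reference_year %||% if (us) 2017L else 2016L
  standard_care_annual <- standard_care_annual %||% if (us) 600 else 180
  background_annual <- background_annual %||% if (us) 4000 else 1200
  if (any(unit_costs < 0) || eqw_price_per_dose < 0) {
    abort("prices must be >= 0")
  }
  if (wholesale_discount < 0 || wholesale_discount >= 1) {
    abort("`wholesale_discount` must lie in [0, 1)")
  }
  if (discount_rate < 0) abort("`discount_rate` must be >= 0")
  structure(list(country = country, unit_costs = unit_costs,
                 eqw_price_per_dose = eqw_price_per_dose,
                 wholesale_discount = wholesale_discount,
                 discount_rate = discount_rate,
                 reference_year = reference_year,
                 standard_care_annual = standard_care_annual,
                 background_annual = background_annual),
            class = "costing_config")
}

#' @rdname costing_config
#' @export
eqw_wholesale_price <- function(costing) {
  costing$eqw_price_per_dose / (1 - costing$wholesale_discount)
}

#' Present value under annual discounting
#'
#' `amount / (1 + rate)^year_index`; year 0 is undiscounted.
#'
#' @param amount Amount accrued (vectorized).
#' @param year_index Whole years since the discounting origin (>= 0).
#' @param rate Annual discount rate (>= 0).
#' @return Present value.
#' @export
#' @examples
#' discount(100, 1, 0.035)  # 96.6184
discount <- function(amount, year_index, rate) {
  if (any(year_index < 0)) abort("`year_index` must be >= 0")
  if (any(rate < 0)) abort("`rate` must be >= 0")
  amount / (1 + rate)^year_index
}

# Integrate a piecewise-linear curve through vertices (t, u), discounting
# each year-k slice by (1+rate)^-k (accrual-year granularity).
discounted_trapz <- function(t, u, rate = 0) {
  if (length(t) < 2) return(0)
  area <- 0
  for (i in seq_len(length(t) - 1)) {
    a <- t[i]; b <- t[i + 1]
    if (b <= a) next
    ints <- if (ceiling(a) <= floor(b)) seq(ceiling(a), floor(b)) else numeric(0)
    cuts <- unique(c(a, ints, b))
    cuts <- sort(cuts[cuts >= a & cuts <= b])
    for (j in seq_len(length(cuts) - 1)) {
      x0 <- cuts[j]; x1 <- cuts[j + 1]
      u0 <- u[i] + (u[i + 1] - u[i]) * (x0 - a) / (b - a)
      u1 <- u[i] + (u[i + 1] - u[i]) * (x1 - a) / (b - a)
      seg <- (x1 - x0) * (u0 + u1) / 2
      area <- area + seg / (1 + rate)^floor(x0 + 1e-12)
    }
  }
  area
}

#' Within-trial QALYs by the area-under-the-curve method
#'
#' Integrates a patient's piecewise-linear utility curve from randomization
#' to the end of follow-up, assuming linear changes in utility between
#' observed time points. If the patient dies, a `(death_time, 0)` vertex is
#' inserted (utility declines linearly from the last observation to zero at
#' death) and utility is zero thereafter. If the patient is censored alive
#' after the last observation, the last observed utility is carried forward
#' flat to the censoring date (set `tail = "truncate"` to instead stop at
#' the last observation). Discounting, when requested, is applied at annual
#' granularity by year of accrual.
#'
#' @param times Observation times, years since randomization, sorted.
#' @param utilities Utility values at those times (no missing values).
#' @param followup_end End of follow-up in years (> 0).
#' @param death_time Death time in years, or `NA` if censored alive.
#' @param discount_rate Annual discount rate (default 0 = undiscounted).
#' @param tail `"carry_forward"` (default) or `"truncate"`.
#' @return QALYs accrued over follow-up (scalar).
#' @export
#' @examples
#' auc_qalys(c(0, 2), c(1, 0), followup_end = 2, death_time = 2)  # 1.0
auc_qalys <- function(times, utilities, followup_end, death_time = NA,
                      discount_rate = 0,
                      tail = c("carry_forward", "truncate")) {
  tail <- match.arg(tail)
  if (length(times) < 1) abort("empty utility series")
  if (length(times) != length(utilities)) abort("times/utilities length mismatch")
  if (anyNA(times) || anyNA(utilities)) abort("utility series contains NA")
  if (is.unsorted(times)) abort("`times` must be sorted")
  if (followup_end <= 0) abort("`followup_end` must be > 0")
  end <- min(followup_end, death_time, na.rm = TRUE)
  if (any(times < 0) || any(times > end + 1e-9)) {
    abort("observation times outside follow-up")
  }
  t <- times; u <- utilities
  died <- !is.na(death_time) && death_time <= followup_end
  last <- length(t)
  if (t[last] < end - 1e-12) {
    if (died) {
      t <- c(t, end); u <- c(u, 0)          # decline to zero at death
    } else if (tail == "carry_forward") {
      t <- c(t, end); u <- c(u, u[last])    # flat to censoring
    }
  }
  if (t[1] > 0) {                           # constant back to time 0
    t <- c(0, t); u <- c(u[1], u)
  }
  discounted_trapz(t, u, discount_rate)
}

#' Within-trial life-years
#'
#' Years alive from randomization to `min(followup_end, death_time)`,
#' discounted at annual granularity.
#'
#' @inheritParams auc_qalys
#' @return Life-years (scalar).
#' @export
life_years_within <- function(followup_end, death_time = NA,
                              discount_rate = 0) {
  end <- min(followup_end, death_time, na.rm = TRUE)
  discounted_trapz(c(0, end), c(1, 1), discount_rate)
}

#' Baseline-utility adjustment of arm QALY means
#'
#' Fits `qalys ~ arm + centered baseline utility` by least squares and
#' returns the adjusted arm means (evaluated at the overall mean baseline
#' utility) and their difference, removing bias from chance baseline
#' imbalance between arms.
#'
#' @param data Data frame with columns `qalys`, `baseline_utility`, `arm`
#'   (values `"active"`/`"control"`).
#' @return A one-row tibble: `mean_active`, `mean_control`, `difference`,
#'   `se_difference`.
#' @export
baseline_adjust <- function(data) {
  stopifnot(all(c("qalys", "baseline_utility", "arm") %in% names(data)))
  if (length(unique(data$arm)) < 2) {
    abort("degenerate design: both arms must be present")
  }
  bc <- data$baseline_utility - mean(data$baseline_utility)
  active <- as.numeric(data$arm == "active")
  fit <- stats::lm(data$qalys ~ active + bc)
  cf <- coef(fit)
  tibble::tibble(mean_active = unname(cf[1] + cf[2]),
                 mean_control = unname(cf[1]),
                 difference = unname(cf[2]),
                 se_difference = summary(fit)$coefficients["active", 2])
}

#' Within-trial costs from resource use
#'
#' Per-patient therapy cost (study-drug doses at the per-dose price plus
#' concomitant diabetes medication units) and other cost (inpatient days,
#' outpatient visits, other medications), each discounted at the configured
#' annual rate by the year in which the resource-use period starts.
#'
#' @param resource_use Resource-use table (`patient_id`, `period_start`,
#'   `period_end`, `inpatient_days`, `outpatient_visits`, `conmed_units`,
#'   `other_med_units`, `study_drug_doses`).
#' @param costing A [costing_config()].
#' @return Tibble with one row per patient: `therapy_cost`, `other_cost`,
#'   `total_cost`.
#' @export
cost_within_trial <- function(resource_use, costing) {
  if (!inherits(costing, "costing_config")) {
    abort("`costing` must be a `costing_config`")
  }
  cnt <- c("inpatient_days", "outpatient_visits", "conmed_units",
           "other_med_units", "study_drug_doses")
  missing_cols <- setdiff(c("patient_id", "period_start", cnt),
                          names(resource_use))
  if (length(missing_cols)) {
    abort(paste0("resource-use table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(resource_use[, cnt])
  if (anyNA(m) || any(m < 0)) abort("resource counts must be non-negative")
  uc <- costing$unit_costs
  df <- 1 / (1 + costing$discount_rate)^floor(resource_use$period_start + 1e-12)
  therapy <- (resource_use$study_drug_doses * costing$eqw_price_per_dose +
                resource_use$conmed_units * uc[["conmed_unit"]]) * df
  other <- (resource_use$inpatient_days * uc[["inpatient_day"]] +
              resource_use$outpatient_visits * uc[["outpatient_visit"]] +
              resource_use$other_med_units * uc[["other_med_unit"]]) * df
  out <- tibble::tibble(patient_id = resource_use$patient_id,
                        therapy = therapy, other = other)
  out <- dplyr::summarise(dplyr::group_by(out, .data$patient_id),
                          therapy_cost = sum(.data$therapy),
                          other_cost = sum(.data$other), .groups = "drop")
  out$total_cost <- out$therapy_cost + out$other_cost
  out
}

#' Per-patient within-trial results across imputations
#'
#' For each completed dataset, computes every patient's discounted QALYs
#' (AUC over the completed utility series), life-years, and costs. Costs do
#' not depend on the imputation (resource use is fully observed) and are
#' computed once, then replicated across imputations.
#'
#' @param cohort A `cea_cohort` (baseline-complete).
#' @param imputations A `cea_imputations` from [impute_chained()].
#' @param costing A [costing_config()].
#' @param tail Censoring-tail rule passed to [auc_qalys()].
#' @return Tibble keyed by (`imputation`, `patient_id`) with `arm`,
#'   `baseline_utility`, `qalys`, `life_years`, `therapy_cost`,
#'   `other_cost`, `total_cost`.
#' @export
within_trial_results <- function(cohort, imputations, costing,
                                 tail = "carry_forward") {
  stop_if_not_cohort(cohort)
  pat <- cohort$patients
  costs <- cost_within_trial(cohort$resource_use, costing)
  costs <- costs[match(pat$patient_id, costs$patient_id), ]
  costs[is.na(costs$therapy_cost), c("therapy_cost", "other_cost",
                                     "total_cost")] <- 0
  rate <- costing$discount_rate
  per_imp <- purrr::map_dfr(seq_len(imputations$m), function(k) {
    ut <- imputations$utilities[[k]]
    ut <- dplyr::arrange(ut, .data$patient_id, .data$visit_time)
    sp <- split(ut[, c("visit_time", "utility")], ut$patient_id)
    ord <- match(pat$patient_id, names(sp))
    q <- purrr::map_dbl(seq_len(nrow(pat)), function(i) {
      s <- sp[[ord[i]]]
      auc_qalys(s$visit_time, s$utility, pat$followup_end[i],
                pat$death_time[i], discount_rate = rate, tail = tail)
    })
    ly <- purrr::map_dbl(seq_len(nrow(pat)), function(i) {
      life_years_within(pat$followup_end[i], pat$death_time[i], rate)
    })
    b0 <- dplyr::filter(ut, .data$visit_time == 0)
    tibble::tibble(imputation = k, patient_id = pat$patient_id,
                   arm = pat$arm,
                   baseline_utility = b0$utility[match(pat$patient_id,
                                                       b0$patient_id)],
                   qalys = q, life_years = ly,
                   therapy_cost = costs$therapy_cost,
                   other_cost = costs$other_cost,
                   total_cost = costs$total_cost)
  })
  per_imp
}
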