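## Uncertainty propagation and cost-effectiveness outputs: patient bootstrap
## crossed with multiple imputation for the within-trial period, coefficient
## draws for the post-trial period, ICERs, percentile CIs, CE plane, CEAC,
## Table-1-style summaries, and scenario machinery.

#' Bootstrap within-trial incremental costs and QALYs
#'
#' Patient-level resampling with replacement, stratified by arm so neither
#' arm can empty, repeated `B` times within each imputed dataset. The
#' baseline-utility adjustment of QALYs is re-fit inside every replicate;
#' cost differences are unadjusted arm means.
#'
#' @param per_patient Per-patient within-trial results from
#'   [within_trial_results()] (columns `imputation`, `patient_id`, `arm`,
#'   `baseline_utility`, `qalys`, `therapy_cost`, `other_cost`,
#'   `total_cost`).
#' @param B Replicates per imputation (default 800).
#' @param seed Integer seed.
#' @return Tibble keyed by (`imputation`, `replicate`) with within-trial
#'   `dcost`, `dcost_therapy`, `dcost_other`, `dqaly`, `dly` and per-arm
#'   absolute means.
#' @export
bootstrap_within_trial <- function(per_patient, B = 800, seed = 1) {
  if (!is_count(B)) abort("`B` must be a positive integer")
  imps <- sort(unique(per_patient$imputation))
  cols <- c("dqaly", "qaly_active", "qaly_control", "dly", "dcost",
            "dcost_therapy", "dcost_other", "cost_active", "cost_control")
  withr::with_seed(child_seed(seed, 211), {
    purrr::map_dfr(imps, function(k) {
      d <- per_patient[per_patient$imputation == k, ]
      ia <- which(d$arm == "active")
      ic <- which(d$arm == "control")
      if (!length(ia) || !length(ic)) abort("both arms must be present")
      qal <- d$qalys
      ly <- d$life_years
      tc <- d$total_cost
      th <- d$therapy_cost
      ot <- d$other_cost
      bu <- d$baseline_utility
      out <- matrix(NA_real_, B, length(cols),
                    dimnames = list(NULL, cols))
      na <- length(ia)
      nc <- length(ic)
      act <- c(rep(1, na), rep(0, nc))
      for (b in seq_len(B)) {
        idx <- c(ia[sample.int(na, na, replace = TRUE)],
                 ic[sample.int(nc, nc, replace = TRUE)])
        X <- cbind(1, act, bu[idx] - mean(bu[idx]))
        cf <- stats::lm.fit(X, qal[idx])$coefficients
        i_a <- idx[seq_len(na)]
        i_c <- idx[na + seq_len(nc)]
        out[b, ] <- c(cf[2], cf[1] + cf[2], cf[1],
                      mean(ly[i_a]) - mean(ly[i_c]),
                      mean(tc[i_a]) - mean(tc[i_c]),
                      mean(th[i_a]) - mean(th[i_c]),
                      mean(ot[i_a]) - mean(ot[i_c]),
                      mean(tc[i_a]), mean(tc[i_c]))
      }
      dplyr::bind_cols(tibble::tibble(imputation = k, replicate = seq_len(B)),
                       tibble::as_tibble(out))
    })
  })
}

#' Combine within-trial and post-trial replicates
#'
#' Adds paired uncertainty replicates elementwise: replicate `b` of every
#' imputation is paired with post-trial coefficient draw `b` (the
#' `"by_replicate"` rule), giving `m x B` lifetime rows on which the
#' identity `lifetime = within + post` holds exactly row-wise. With
#' `pairing = "shared"` the post draws are recycled in order if fewer post
#' rows than `B` are supplied.
#'
#' @param within Replicates from [bootstrap_within_trial()].
#' @param post Post-trial per-draw increments: tibble with `draw`, `dcost`,
#'   `dqaly`, optionally `dly`, `dcost_therapy`, `dcost_other` (draw 0 =
#'   point estimate, excluded from pairing).
#' @param pairing `"by_replicate"` (default) or `"shared"`.
#' @return A `replicate_table` tibble with `within_*`, `post_*` and
#'   `lifetime_*` columns.
#' @export
combine_periods <- function(within, post,
                            pairing = c("by_replicate", "shared")) {
  pairing <- match.arg(pairing)
  post <- post[post$draw > 0, , drop = FALSE]
  if (nrow(post) == 0) abort("no post-trial draws supplied")
  B <- max(within$replicate)
  if (pairing == "by_replicate" && nrow(post) < B) {
    abort("fewer post-trial draws than bootstrap replicates; use pairing = \"shared\"")
  }
  j <- ((within$replicate - 1) %% nrow(post)) + 1
  out <- tibble::tibble(
    imputation = within$imputation, replicate = within$replicate,
    within_dcost = within$dcost, within_dqaly = within$dqaly,
    within_dly = within$dly %||% NA_real_,
    post_dcost = post$dcost[j], post_dqaly = post$dqaly[j],
    post_dly = (post$dly %||% rep(NA_real_, nrow(post)))[j])
  out$lifetime_dcost <- out$within_dcost + out$post_dcost
  out$lifetime_dqaly <- out$within_dqaly + out$post_dqaly
  out$lifetime_dly <- out$within_dly + out$post_dly
  structure(out, class = c("replicate_table", class(out)))
}

#' Incremental cost-effectiveness ratio with quadrant label
#'
#' The ratio `dcost / dqaly` is reported only when `dqaly > 0`; otherwise
#' it is undefined (`NA`) and the quadrant label carries the information.
#' Quadrants on the cost-effectiveness plane: `NE` (more costly, more
#' effective), `SE (dominant)` (cheaper, more effective), `NW (dominated)`
#' (more costly, less or equally effective), `SW` (cheaper, less
#' effective).
#'
#' @param dcost,dqaly Incremental cost and QALYs (vectorized).
#' @return Tibble with `dcost`, `dqaly`, `icer`, `quadrant`.
#' @export
#' @examples
#' icer(6357, 0.151)   # about 42,099 per QALY, NE
icer <- function(dcost, dqaly) {
  quadrant <- dplyr::case_when(
    dqaly > 0 & dcost >= 0 ~ "NE",
    dqaly > 0 & dcost < 0 ~ "SE (dominant)",
    dqaly <= 0 & dcost > 0 ~ "NW (dominated)",
    TRUE ~ "SW")
  tibble::tibble(dcost = dcost, dqaly = dqaly,
                 icer = ifelse(dqaly > 0, dcost / dqaly, NA_real_),
                 quadrant = quadrant)
}

#' Percentile confidence bounds over pooled replicates
#'
#' Empirical percentiles (linear-interpolation type 7 rule, fixed for
#' reproducibility) of the pooled bootstrap-times-imputation values.
#'
#' @param values Numeric replicate values (pooled over imputations).
#' @param probs Percentile pair (default 2.5th and 97.5th).
#' @return Named numeric vector of bounds.
#' @export
percentile_ci <- function(values, probs = c(0.025, 0.975)) {
  if (length(values) == 0) abort("no replicate values supplied")
  quantile(values, probs = probs, type = 7, names = TRUE, na.rm = FALSE)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold `lambda`, the fraction of
#' replicates with positive net monetary benefit
#' `lambda * dqaly - dcost > 0`, pooled across all bootstraps of all
#' imputations.
#'
#' @param replicates A `replicate_table` (or any data frame with the chosen
#'   columns).
#' @param thresholds Willingness-to-pay grid (default 0 to 300,000 in steps
#'   of 1,000, covering the commonly cited 100,000 USD and 20,000 GBP
#'   references).
#' @param cost_col,qaly_col Which increments to use.
#' @return Tibble `threshold`, `probability`.
#' @export
ceac <- function(replicates, thresholds = seq(0, 3e5, by = 1e3),
                 cost_col = "lifetime_dcost", qaly_col = "lifetime_dqaly") {
  if (any(thresholds < 0)) abort("`thresholds` must be >= 0")
  dc <- replicates[[cost_col]]
  dq <- replicates[[qaly_col]]
  tibble::tibble(
    threshold = thresholds,
    probability = vapply(thresholds,
                         function(l) mean(l * dq - dc > 0), numeric(1)))
}

#' Table-1-style lifetime summary
#'
#' Assembles the within-trial / post-trial / lifetime summary for each
#' quantity: per-arm means, arm differences (active minus control), with
#' `lifetime = within + post` per arm and `total = therapy + other` for
#' costs enforced by construction. Inputs are checked for consistency: if a
#' `total_cost` component is supplied it must equal therapy + other.
#'
#' @param components Tibble with columns `quantity` (`therapy_cost`,
#'   `other_cost`, `total_cost`, `qalys`, `life_years`), `period`
#'   (`within`, `post`), `arm` (`active`, `control`) and `value`.
#' @param tol Consistency tolerance for a supplied `total_cost`.
#' @return Tibble with one row per quantity and period (`within`, `post`,
#'   `lifetime`): `active`, `control`, `difference`.
#' @export
lifetime_table <- function(components, tol = 1e-6) {
  need <- c("quantity", "period", "arm", "value")
  stopifnot(all(need %in% names(components)))
  comp <- tibble::as_tibble(components)
  get <- function(q, p, a) {
    v <- comp$value[comp$quantity == q & comp$period == p & comp$arm == a]
    if (length(v) == 0) NA_real_ else v[1]
  }
  # derive total = therapy + other; a supplied total must agree
  if (all(c("therapy_cost", "other_cost") %in% comp$quantity)) {
    derived <- purrr::map_dfr(c("within", "post"), function(p) {
      purrr::map_dfr(c("active", "control"), function(a) {
        tot <- get("therapy_cost", p, a) + get("other_cost", p, a)
        sup <- get("total_cost", p, a)
        if (!is.na(sup) && !is.na(tot) &&
            abs(sup - tot) > tol * max(1, abs(tot))) {
          abort("inconsistent components: total_cost != therapy + other")
        }
        tibble::tibble(quantity = "total_cost", period = p, arm = a,
                       value = tot)
      })
    })
    comp <- dplyr::bind_rows(comp[comp$quantity != "total_cost", ],
                             derived[!is.na(derived$value), ])
  }
  out <- purrr::map_dfr(unique(comp$quantity), function(q) {
    w_a <- get(q, "within", "active"); w_c <- get(q, "within", "control")
    p_a <- get(q, "post", "active"); p_c <- get(q, "post", "control")
    p_a <- ifelse(is.na(p_a), 0, p_a); p_c <- ifelse(is.na(p_c), 0, p_c)
    tibble::tibble(quantity = q,
                   period = c("within", "post", "lifetime"),
                   active = c(w_a, p_a, w_a + p_a),
                   control = c(w_c, p_c, w_c + p_c))
  })
  out$difference <- out$active - out$control
  out
}

#' Scenario grid for sensitivity and subgroup analyses
#'
#' Builds a named list of configuration deltas covering the standard
#' sensitivity machinery: study-drug price discounts (default 20-80%),
#' treatment-discontinuation scenarios, discount-rate variants, trajectory
#' modes, and subgroup filters (UK/US sites only, age >= 65, diabetes
#' duration < 5 years, prior cardiovascular disease).
#'
#' @param price_discounts Fractions taken off the study-drug price.
#' @param discontinuation Scenario names to include.
#' @param discount_rates Alternative annual discount rates (applied to both
#'   costs and effects).
#' @param subgroups Named list of predicate functions over the patients
#'   table, or `TRUE` for the standard set.
#' @return Named list of scenario descriptors for [run_scenarios()].
#' @export
scenario_grid <- function(price_discounts = c(0.2, 0.4, 0.6, 0.8),
                          discontinuation = c("scenario1", "scenario2"),
                          discount_rates = numeric(0),
                          subgroups = TRUE) {
  sc <- list()
  for (f in price_discounts) {
    sc[[sprintf("price_discount_%.0f", 100 * f)]] <-
      list(type = "price_discount", fraction = f)
  }
  for (s in discontinuation) {
    sc[[s]] <- list(type = "discontinuation", scenario = s)
  }
  for (r in discount_rates) {
    sc[[sprintf("discount_rate_%.1f", 100 * r)]] <-
      list(type = "discount_rate", rate = r)
  }
  if (isTRUE(subgroups)) {
    subgroups <- list(
      uk_sites = function(p) p$country_setting == "UK",
      us_sites = function(p) p$country_setting == "US",
      age_ge_65 = function(p) p$age >= 65,
      duration_lt_5 = function(p) p$diabetes_duration < 5,
      prior_cvd = function(p) p$prior_cvd)
  }
  if (is.list(subgroups)) {
    for (nm in names(subgroups)) {
      sc[[paste0("subgroup_", nm)]] <-
        list(type = "subgroup", predicate = subgroups[[nm]])
    }
  }
  sc
}
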