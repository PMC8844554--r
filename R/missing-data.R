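## Missing-data handling: deterministic baseline imputation, chained-equation
## multiple imputation with predictive mean matching for post-baseline
## utilities and risk factors (run separately), and across-imputation
## averaging of risk factors for the simulation input.

#' Multiple-imputation configuration
#'
#' @param m Number of imputed datasets (default 28, matching the convention
#'   of one imputation per percentage point of missing utility data at 28%
#'   missingness).
#' @param chained_iterations Gibbs-style sweeps of the chained equations.
#' @param donors Donor pool size for predictive mean matching.
#' @param continuous_method `"pmm"` (predictive mean matching; bounded and
#'   distribution-preserving, the default because utilities are bounded and
#'   skewed) or `"linear"` (normal-theory draws).
#' @param seed Integer seed.
#' @return A list of class `imputation_config`.
#' @export
imputation_config <- function(m = 28, chained_iterations = 10, donors = 5,
                              continuous_method = c("pmm", "linear"),
                              seed = 1) {
  continuous_method <- match.arg(continuous_method)
  if (!is_count(m) || m < 1) abort("`m` must be a positive integer")
  if (!is_count(chained_iterations)) abort("`chained_iterations` must be >= 1")
  if (!is_count(donors)) abort("`donors` must be >= 1")
  structure(list(m = as.integer(m),
                 chained_iterations = as.integer(chained_iterations),
                 donors = as.integer(donors),
                 continuous_method = continuous_method,
                 seed = as.integer(seed)),
            class = "imputation_config")
}

#' Deterministic baseline imputation
#'
#' Fills missing baseline values by simple rules: baseline EQ-5D utility,
#' height and weight by the sex-stratified mean of observed values (falling
#' back, with a message, to the overall mean if a sex stratum has no
#' observed values); smoking status by the per-country mode. No other cells
#' are touched. Requires utilities to have been valued first with
#' [add_utility_values()].
#'
#' @param cohort A `cea_cohort` with valued utilities.
#' @return The cohort with complete baseline utility, height, weight and
#'   smoking.
#' @export
impute_baseline <- function(cohort) {
  stop_if_not_cohort(cohort)
  if (is.null(cohort$utilities$utility)) {
    abort("utilities are not valued; run `add_utility_values()` first")
  }
  pat <- cohort$patients
  ut <- cohort$utilities

  sex_of <- pat$sex[match(ut$patient_id, pat$patient_id)]
  b <- ut$visit_time == 0
  for (s in unique(pat$sex)) {
    sel <- b & sex_of == s & is.na(ut$utility)
    if (any(sel)) {
      obs <- ut$utility[b & sex_of == s & !is.na(ut$utility)]
      if (length(obs) == 0) {
        inform(paste0("no observed baseline utilities for sex '", s,
                      "'; falling back to overall mean"))
        obs <- ut$utility[b & !is.na(ut$utility)]
      }
      ut$utility[sel] <- mean(obs)
    }
  }

  for (f in c("height", "weight")) {
    for (s in unique(pat$sex)) {
      sel <- pat$sex == s & is.na(pat[[f]])
      if (any(sel)) {
        obs <- pat[[f]][pat$sex == s & !is.na(pat[[f]])]
        if (length(obs) == 0) {
          inform(paste0("no observed ", f, " for sex '", s,
                        "'; falling back to overall mean"))
          obs <- pat[[f]][!is.na(pat[[f]])]
        }
        pat[[f]][sel] <- mean(obs)
      }
    }
  }

  for (co in unique(pat$country_setting)) {
    sel <- pat$country_setting == co & is.na(pat$smoking)
    if (any(sel)) {
      obs <- pat$smoking[pat$country_setting == co & !is.na(pat$smoking)]
      if (length(obs) == 0) obs <- pat$smoking[!is.na(pat$smoking)]
      tab <- sort(table(obs), decreasing = TRUE)
      pat$smoking[sel] <- names(tab)[1]
    }
  }

  cohort$patients <- pat
  cohort$utilities <- ut
  cohort
}

## ---- chained-equations engine ----------------------------------------------

# One Bayesian linear-regression imputation step with predictive mean
# matching (type-1 matching: observed predictions from the posterior mode,
# missing predictions from a parameter draw). X must include an intercept.
pmm_step <- function(X, y, obs, mis, donors, method) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  qrx <- qr(Xo)
  rank <- qrx$rank
  used <- qrx$pivot[seq_len(rank)]
  betahat <- qr.coef(qrx, yo)[used]
  res <- yo - Xo[, used, drop = FALSE] %*% betahat
  df <- max(length(yo) - rank, 1)
  sigma2 <- sum(res^2) / df
  sigma2_star <- sum(res^2) / rchisq(1, df)
  XtXi <- chol2inv(qr.R(qrx)[seq_len(rank), seq_len(rank), drop = FALSE])
  beta_star <- betahat + drop(t(chol(sigma2_star * XtXi +
                                       diag(1e-12, rank))) %*% rnorm(rank))
  yhat_mis <- drop(X[mis, used, drop = FALSE] %*% beta_star)
  if (method == "linear") {
    return(yhat_mis + rnorm(length(yhat_mis), 0, sqrt(sigma2_star)))
  }
  yhat_obs <- drop(Xo[, used, drop = FALSE] %*% betahat)
  ord <- order(yhat_obs)
  ys <- yo[ord]
  ps <- yhat_obs[ord]
  k <- min(donors, length(ys))
  vapply(yhat_mis, function(p) {
    i <- findInterval(p, ps)
    lo <- max(1, i - k)
    hi <- min(length(ps), i + k)
    cand <- lo:hi
    near <- cand[order(abs(ps[cand] - p))][seq_len(k)]
    ys[sample(near, 1)]
  }, numeric(1))
}

# Chained imputation over the visit columns of one wide matrix W
# (rows = patients, columns = visits in time order). `occ` marks cells whose
# visit occurred; `need` marks occurred cells whose value is missing.
# Column 1 (baseline) must be complete. Predictors: Z plus the previous
# visit's current value (the variable's own lag).
chained_impute_wide <- function(W, occ, need, Z, iterations, donors, method) {
  p <- ncol(W)
  cols <- which(colSums(need) > 0)
  for (v in cols) {
    obs_v <- occ[, v] & !need[, v]
    if (!any(obs_v)) {
      abort(paste0("no observed values at visit column ", v,
                   "; cannot impute"))
    }
    W[need[, v], v] <- sample(W[obs_v, v], sum(need[, v]), replace = TRUE)
  }
  for (it in seq_len(iterations)) {
    for (v in cols) {
      rows <- occ[, v]
      obs <- rows & !need[, v]
      mis <- rows & need[, v]
      if (!any(mis)) next
      X <- cbind(1, Z, lag = W[, v - 1])
      W[mis, v] <- pmm_step(X, W[, v], obs, mis, donors, method)
    }
  }
  W
}

baseline_design <- function(cohort) {
  pat <- cohort$patients
  ut <- cohort$utilities
  b <- ut[ut$visit_time == 0, ]
  u0 <- b$utility[match(pat$patient_id, b$patient_id)]
  cbind(active = as.numeric(pat$arm == "active"),
        age = pat$age,
        female = as.numeric(pat$sex == "female"),
        diabetes_duration = pat$diabetes_duration,
        prior_cvd = as.numeric(pat$prior_cvd),
        baseline_utility = u0)
}

#' Chained-equation multiple imputation of post-baseline values
#'
#' Produces `m` completed datasets by iterative chained-equation imputation
#' with predictive mean matching. Post-baseline EQ-5D utilities and each
#' continuous risk factor are imputed in separate chained runs. For each
#' visit the regression predictors are arm, age, sex, diabetes duration,
#' prior cardiovascular disease, baseline utility, and the variable's own
#' previous-visit value. Observed cells are passed through untouched in
#' every completed copy; under predictive mean matching every imputed value
#' equals some observed donor's value.
#'
#' @param cohort A `cea_cohort` with valued utilities and complete baseline
#'   (after [impute_baseline()]).
#' @param config An [imputation_config()].
#' @return An object of class `cea_imputations`: lists `utilities` and
#'   `risk_factors` of `m` completed long tibbles (with an `imputed` flag
#'   per cell), plus the config.
#' @export
impute_chained <- function(cohort, config = imputation_config()) {
  stop_if_not_cohort(cohort)
  if (!inherits(config, "imputation_config")) {
    abort("`config` must be created by `imputation_config()`")
  }
  ut <- cohort$utilities
  if (is.null(ut$utility)) abort("utilities are not valued")
  if (anyNA(ut$utility[ut$visit_time == 0])) {
    abort("baseline utilities incomplete; run `impute_baseline()` first")
  }
  Z <- baseline_design(cohort)
  pat_ids <- cohort$patients$patient_id

  # utilities wide: rows = patients, cols = scheduled visit times
  times <- sort(unique(ut$visit_time))
  Wu <- matrix(NA_real_, length(pat_ids), length(times),
               dimnames = list(pat_ids, paste0("t", times)))
  ij <- cbind(match(ut$patient_id, pat_ids), match(ut$visit_time, times))
  Wu[ij] <- ut$utility
  occ_u <- matrix(FALSE, length(pat_ids), length(times))
  occ_u[ij] <- TRUE
  need_u <- occ_u & is.na(Wu)

  rf <- cohort$risk_factors
  rf_times <- sort(unique(rf$visit_time))
  factors <- sort(unique(rf$factor))
  rf_mats <- purrr::map(factors, function(f) {
    sub <- rf[rf$factor == f, ]
    W <- matrix(NA_real_, length(pat_ids), length(rf_times))
    ij <- cbind(match(sub$patient_id, pat_ids),
                match(sub$visit_time, rf_times))
    W[ij] <- sub$value
    occ <- matrix(FALSE, length(pat_ids), length(rf_times))
    occ[ij] <- TRUE
    list(W = W, occ = occ, need = occ & is.na(W), ij = ij, sub = sub)
  })
  names(rf_mats) <- factors

  completed_u <- vector("list", config$m)
  completed_rf <- vector("list", config$m)
  for (k in seq_len(config$m)) {
    withr::with_seed(child_seed(config$seed, 1000 + k), {
      Wk <- chained_impute_wide(Wu, occ_u, need_u, Z,
                                config$chained_iterations, config$donors,
                                config$continuous_method)
      uk <- ut
      uk$utility <- Wk[ij]
      uk$imputed <- need_u[ij]
      completed_u[[k]] <- uk[, c("patient_id", "visit_time", "instrument",
                                 "utility", "imputed")]

      # risk factors: separate chained run per factor
      parts <- purrr::map(factors, function(f) {
        mt <- rf_mats[[f]]
        Zf <- cbind(Z, rf_baseline = mt$W[, 1])
        Wf <- if (any(mt$need)) {
          chained_impute_wide(mt$W, mt$occ, mt$need, Zf,
                              config$chained_iterations, config$donors,
                              config$continuous_method)
        } else mt$W
        out <- mt$sub
        out$value <- Wf[mt$ij]
        out$imputed <- mt$need[mt$ij]
        out
      })
      completed_rf[[k]] <- if (length(parts)) {
        dplyr::arrange(dplyr::bind_rows(parts), .data$patient_id,
                       .data$factor, .data$visit_time)
      } else {
        dplyr::mutate(rf, imputed = logical(0))
      }
    })
  }
  structure(list(m = config$m, utilities = completed_u,
                 risk_factors = completed_rf, config = config),
            class = "cea_imputations")
}

#' @export
print.cea_imputations <- function(x, ...) {
  cat("<cea_imputations> m =", x$m, "completed datasets;",
      sum(x$utilities[[1]]$imputed), "imputed utility cells,",
      sum(x$risk_factors[[1]]$imputed), "imputed risk-factor cells\n")
  invisible(x)
}

#' Average imputed risk factors across completions
#'
#' Collapses `m` completed risk-factor tables to a single table: observed
#' cells pass through unchanged, imputed cells are replaced by their
#' across-imputation arithmetic mean. The result has no missing values and
#' feeds the extrapolation engine's end-of-trial profiles.
#'
#' @param imputations A `cea_imputations` object, or a list of completed
#'   risk-factor tibbles (columns `patient_id`, `visit_time`, `factor`,
#'   `value`, `imputed`).
#' @return One risk-factor tibble with columns `patient_id`, `visit_time`,
#'   `factor`, `value`, `imputed`.
#' @export
average_risk_factor_imputations <- function(imputations) {
  tabs <- if (inherits(imputations, "cea_imputations")) {
    imputations$risk_factors
  } else {
    imputations
  }
  if (length(tabs) < 1) abort("need at least one completed dataset")
  ref <- tabs[[1]]
  key <- paste(ref$patient_id, ref$factor, ref$visit_time)
  vals <- purrr::map(tabs, function(t) {
    if (nrow(t) != nrow(ref) ||
        !identical(paste(t$patient_id, t$factor, t$visit_time), key)) {
      abort("completed datasets have inconsistent shapes")
    }
    t$value
  })
  out <- ref
  out$value <- Reduce(`+`, vals) / length(vals)
  out$value[!ref$imputed] <- ref$value[!ref$imputed]
  if (anyNA(out$value)) abort("averaged risk-factor table still has missing values")
  out
}
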