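## Parametric annual risk equations for complications and death, and
## multivariate-normal coefficient draws for parameter uncertainty.
##
## The engine accepts any coefficient file with the documented schema; the
## packaged defaults are synthetic placeholders with realistic structure,
## not the published outcomes-model coefficients.

risk_equation_forms <- c("exponential", "weibull", "gompertz", "logistic")

allowed_equation_terms <- function() {
  c("intercept", risk_factor_registry(), "age", "duration", "female",
    "prior_cvd", paste0("hist_", complication_registry()), "on_drug")
}

#' Read a risk-equation coefficient table
#'
#' Schema: one row per term per equation, columns `equation` (a
#' complication from [complication_registry()] or `death`), `form`
#' (`exponential`, `weibull`, `gompertz` or `logistic`), `shape` (shape
#' parameter for weibull/gompertz; NA otherwise), `term` (see
#' `allowed` terms in Details), `estimate`, and optional `ref` (centering
#' constant subtracted from the covariate; default 0).
#'
#' The linear predictor for a profile is
#' `sum(estimate * (value - ref))` with `intercept` contributing its
#' estimate directly. Allowed terms: `intercept`, the risk factors of
#' [risk_factor_registry()], `age`, `duration`, `female`, `prior_cvd`,
#' first-event history flags `hist_<complication>`, and `on_drug`.
#'
#' @param path CSV file path.
#' @return A tibble of class `risk_equations`.
#' @export
read_risk_equations <- function(path) {
  eq <- readr::read_csv(path, show_col_types = FALSE)
  validate_risk_equations(eq)
}

#' @rdname read_risk_equations
#' @param equations A data frame in the schema above.
#' @export
validate_risk_equations <- function(equations) {
  eq <- tibble::as_tibble(equations)
  stopifnot(all(c("equation", "form", "term", "estimate") %in% names(eq)))
  if (is.null(eq$shape)) eq$shape <- NA_real_
  if (is.null(eq$ref)) eq$ref <- 0
  eq$ref[is.na(eq$ref)] <- 0
  bad <- setdiff(eq$form, risk_equation_forms)
  if (length(bad)) abort(paste0("unknown form(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(eq$equation, c(complication_registry(), "death"))
  if (length(bad)) abort(paste0("unknown equation outcome(s): ",
                                paste(bad, collapse = ", ")))
  bad <- setdiff(eq$term, allowed_equation_terms())
  if (length(bad)) {
    abort(paste0("coefficient term(s) not in the registry: ",
                 paste(bad, collapse = ", ")))
  }
  for (e in unique(eq$equation)) {
    sub <- eq[eq$equation == e, ]
    if (length(unique(sub$form)) != 1) {
      abort(paste0("equation ", e, " mixes functional forms"))
    }
    if (sub$form[1] %in% c("weibull", "gompertz") &&
        (is.na(sub$shape[1]) || sub$shape[1] <= 0)) {
      abort(paste0("equation ", e, " needs a positive shape parameter"))
    }
    if (anyDuplicated(sub$term)) {
      abort(paste0("equation ", e, " has duplicated terms"))
    }
  }
  structure(eq, class = c("risk_equations", class(eq)))
}

#' Packaged synthetic risk equations and complication tables
#'
#' Loads the synthetic placeholder coefficient file shipped with the
#' package (eight diabetes complications plus death, exponential and
#' weibull forms, realistic magnitudes). These illustrate the schema and
#' drive the packaged demo; they are not the published outcomes-model
#' coefficients, which users can supply via [read_risk_equations()].
#'
#' @return A `risk_equations` tibble.
#' @export
default_risk_equations <- function() {
  read_risk_equations(system.file("extdata", "risk_equations_synthetic.csv",
                                  package = "trialcea", mustWork = TRUE))
}

#' Annual event probability from a risk equation
#'
#' Bridges a parametric hazard to a one-year event probability. For the
#' exponential form the annual hazard is `lambda = exp(lp)` and
#' `p = 1 - exp(-lambda)`. Weibull and gompertz forms use the cumulative
#' hazard increment over the year, `p = 1 - exp(-(H(t+1) - H(t)))`, on the
#' diabetes-duration time scale `t`, with `H(t) = exp(lp) * t^shape`
#' (weibull) or `H(t) = exp(lp)/shape * (exp(shape*t) - 1)` (gompertz).
#' The logistic form returns the fitted probability `plogis(lp)` directly.
#'
#' @param equations A `risk_equations` table (rows for one equation).
#' @param profile Named list/vector of covariate values covering every
#'   non-intercept term of the equation (e.g. `age`, risk factors,
#'   `hist_mi` flags, `on_drug`).
#' @param outcome Which equation to evaluate (defaults to the only one
#'   present).
#' @return Annual event probability in `[0, 1]` (vectorized over profiles
#'   supplied as a data frame).
#' @export
#' @examples
#' eq <- validate_risk_equations(data.frame(
#'   equation = "death", form = "exponential", shape = NA,
#'   term = "intercept", estimate = log(0.05), ref = 0))
#' annual_event_probability(eq, list())  # 1 - exp(-0.05)
annual_event_probability <- function(equations, profile, outcome = NULL) {
  eq <- tibble::as_tibble(equations)
  if (!is.null(outcome)) eq <- eq[eq$equation == outcome, ]
  if (length(unique(eq$equation)) != 1) {
    abort("supply rows for exactly one equation (or set `outcome`)")
  }
  prof <- tibble::as_tibble(as.list(profile))
  n <- max(1, nrow(prof))
  lp <- rep(0, n)
  for (i in seq_len(nrow(eq))) {
    if (eq$term[i] == "intercept") {
      lp <- lp + eq$estimate[i]
    } else {
      if (is.null(prof[[eq$term[i]]])) {
        abort(paste0("profile lacks risk-factor term `", eq$term[i], "`"))
      }
      lp <- lp + eq$estimate[i] * (prof[[eq$term[i]]] - eq$ref[i])
    }
  }
  if (any(!is.finite(lp))) abort("non-finite linear predictor")
  form <- eq$form[1]
  if (form == "logistic") return(plogis(lp))
  if (form == "exponential") return(1 - exp(-exp(lp)))
  t <- prof[["duration"]] %||% abort("weibull/gompertz forms need `duration`")
  shape <- eq$shape[1]
  H <- function(t) {
    if (form == "weibull") exp(lp) * t^shape
    else exp(lp) / shape * (exp(shape * t) - 1)
  }
  pmin(pmax(1 - exp(-(H(t + 1) - H(t))), 0), 1)
}

#' Default diagonal coefficient covariance
#'
#' A simple parameter-uncertainty specification when no estimated
#' covariance is available: independent normal uncertainty on each
#' equation's intercept (standard deviation `sd_intercept` on the log-rate
#' scale, i.e. roughly a proportional standard error on the annual rate)
#' and optionally on the other coefficients.
#'
#' @param equations A `risk_equations` table.
#' @param sd_intercept Standard deviation for intercept terms.
#' @param sd_other Standard deviation for non-intercept terms.
#' @return A diagonal covariance matrix for [draw_coefficients()].
#' @export
default_coef_covariance <- function(equations, sd_intercept = 0.05,
                                    sd_other = 0) {
  eq <- validate_risk_equations(equations)
  ids <- paste(eq$equation, eq$term, sep = ":")
  v <- ifelse(eq$term == "intercept", sd_intercept^2, sd_other^2)
  keep <- v > 0
  if (!any(keep)) return(NULL)
  diag(v[keep], sum(keep)) |>
    (\(m) {dimnames(m) <- list(ids[keep], ids[keep]); m})()
}

#' Read a coefficient covariance matrix
#'
#' CSV with a `term_id` column (`"<equation>:<term>"`) and one numeric
#' column per term id, forming a symmetric matrix for [draw_coefficients()].
#'
#' @param path CSV file path.
#' @return A named square matrix.
#' @export
read_coef_covariance <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(x[, -1])
  rownames(m) <- x[[1]]
  if (!identical(rownames(m), colnames(m))) {
    abort("covariance rows and columns must carry identical term ids")
  }
  m
}

#' Draw risk-equation coefficient sets
#'
#' Multivariate-normal draws around the point estimates, propagating
#' parameter uncertainty around the risk equations. Draw 0 (the first list
#' element) is reserved for the point estimates themselves.
#'
#' @param equations A `risk_equations` table.
#' @param covariance Square covariance matrix with dimnames
#'   `"<equation>:<term>"` covering any subset of the coefficients
#'   (uncovered coefficients are held fixed), or `NULL` for no uncertainty.
#' @param n_draws Number of stochastic draws.
#' @param seed Integer seed.
#' @return A list of `n_draws + 1` `risk_equations` tables; element 1 is
#'   the point estimate.
#' @export
draw_coefficients <- function(equations, covariance = NULL, n_draws, seed = 1) {
  eq <- validate_risk_equations(equations)
  if (!is_count(n_draws, positive = FALSE)) abort("`n_draws` must be a count")
  ids <- paste(eq$equation, eq$term, sep = ":")
  out <- vector("list", n_draws + 1)
  out[[1]] <- eq
  if (is.null(covariance) || n_draws == 0 || all(covariance == 0)) {
    for (d in seq_len(n_draws)) out[[d + 1]] <- eq
    return(out)
  }
  cov_ids <- rownames(covariance)
  bad <- setdiff(cov_ids, ids)
  if (length(bad)) {
    abort(paste0("covariance term id(s) not in the coefficient table: ",
                 paste(bad, collapse = ", ")))
  }
  S <- (covariance + t(covariance)) / 2
  ev <- eigen(S, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values)))) {
    abort("covariance matrix is not positive semi-definite")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S))
  idx <- match(cov_ids, ids)
  withr::with_seed(seed, {
    for (d in seq_len(n_draws)) {
      z <- drop(L %*% rnorm(nrow(S)))
      eqd <- eq
      eqd$estimate[idx] <- eq$estimate[idx] + z
      out[[d + 1]] <- eqd
    }
  })
  out
}
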