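## Table readers/writers, validation, the run manifest, and the command-line
## entry point tying the stages into one reproducible pipeline run. CSV is
## the interchange format between stages (inspectable, language-neutral).

#' Write / read a cohort as CSV tables
#'
#' Writes the five cohort tables (`patients`, `utilities`, `resource_use`,
#' `events`, `risk_factors`) as CSV files plus the ground truth (when
#' present) as JSON, and reads them back. All times are decimal years since
#' randomization.
#'
#' @param cohort A `cea_cohort`.
#' @param dir Directory to write to / read from.
#' @return `write_cohort()` returns the directory invisibly;
#'   `read_cohort()` returns a `cea_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stop_if_not_cohort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in c("patients", "utilities", "resource_use", "events",
              "risk_factors")) {
    readr::write_csv(cohort[[t]], file.path(dir, paste0(t, ".csv")))
  }
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    gt$config <- unclass(gt$config)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tabs <- purrr::map(c(patients = "patients", utilities = "utilities",
                       resource_use = "resource_use", events = "events",
                       risk_factors = "risk_factors"), function(t) {
    f <- file.path(dir, paste0(t, ".csv"))
    if (!file.exists(f)) abort(paste0("missing input table: ", f))
    readr::read_csv(f, show_col_types = FALSE)
  })
  gt_file <- file.path(dir, "ground_truth.json")
  tabs$ground_truth <- if (file.exists(gt_file)) {
    jsonlite::read_json(gt_file, simplifyVector = TRUE)
  }
  tabs$masks <- NULL
  structure(tabs, class = "cea_cohort")
}

#' Validate cohort tables against the schema registry
#'
#' Checks column presence, value ranges, time monotonicity and referential
#' integrity across tables. Always returns a report (possibly empty); the
#' caller decides fatality.
#'
#' @param cohort A `cea_cohort` (or a directory readable by
#'   [read_cohort()]).
#' @return Tibble of violations: `table`, `rule`, `patient_id`, `message`.
#' @export
validate_tables <- function(cohort) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stop_if_not_cohort(cohort)
  v <- list()
  add <- function(table, rule, ids, msg) {
    if (length(ids)) {
      v[[length(v) + 1]] <<- tibble::tibble(
        table = table, rule = rule, patient_id = ids, message = msg)
    }
  }
  p <- cohort$patients
  need <- c("patient_id", "arm", "age", "sex", "diabetes_duration",
            "followup_end")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    add("patients", "columns", NA_character_,
        paste0("missing column(s): ", paste(miss, collapse = ", ")))
  } else {
    add("patients", "age_positive", p$patient_id[!is.na(p$age) & p$age <= 0],
        "age must be > 0")
    add("patients", "duration_nonneg",
        p$patient_id[!is.na(p$diabetes_duration) & p$diabetes_duration < 0],
        "diabetes_duration must be >= 0")
    add("patients", "followup_range",
        p$patient_id[is.na(p$followup_end) | p$followup_end <= 0 |
                       p$followup_end > 6.7],
        "followup_end must lie in (0, 6.7]")
    add("patients", "death_within_followup",
        p$patient_id[!is.na(p$death_time) &
                       p$death_time > p$followup_end + 1e-9],
        "death_time must be <= followup_end")
    add("patients", "arm_values",
        p$patient_id[!p$arm %in% c("active", "control")],
        "arm must be active/control")

    u <- cohort$utilities
    fe <- p$followup_end[match(u$patient_id, p$patient_id)]
    add("utilities", "id_integrity",
        unique(u$patient_id[!u$patient_id %in% p$patient_id]),
        "patient_id not in patients table")
    add("utilities", "visit_within_followup",
        unique(u$patient_id[!is.na(fe) & u$visit_time > fe + 1e-9 &
                              u$visit_time > 0]),
        "visit_time exceeds followup_end")
    for (d in intersect(eq5d_dimensions(), names(u))) {
      top <- ifelse(u$instrument == "EQ5D5L", 5L, 3L)
      bad <- !is.na(u[[d]]) & (u[[d]] < 1 | u[[d]] > top)
      add("utilities", paste0("level_range_", d), unique(u$patient_id[bad]),
          "level outside instrument range")
    }

    r <- cohort$resource_use
    cnt <- intersect(c("inpatient_days", "outpatient_visits", "conmed_units",
                       "other_med_units", "study_drug_doses"), names(r))
    for (cc in cnt) {
      add("resource_use", paste0("nonneg_", cc),
          unique(r$patient_id[!is.na(r[[cc]]) & r[[cc]] < 0]),
          "counts must be >= 0")
    }
    ov <- dplyr::group_by(r, .data$patient_id)
    ov <- dplyr::summarise(ov, bad = any(.data$period_start <
                                           dplyr::lag(.data$period_end,
                                                      default = -Inf)),
                           .groups = "drop")
    add("resource_use", "periods_nonoverlapping",
        ov$patient_id[ov$bad], "periods overlap")

    e <- cohort$events
    add("events", "id_integrity",
        unique(e$patient_id[!e$patient_id %in% p$patient_id]),
        "patient_id not in patients table")
    add("events", "time_within_followup",
        unique(e$patient_id[e$time > fe_of(e$patient_id, p) + 1e-9]),
        "event time exceeds followup_end")
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(table = character(), rule = character(),
                   patient_id = character(), message = character())
  }
}

fe_of <- function(ids, patients) {
  patients$followup_end[match(ids, patients$patient_id)]
}

#' Run manifest
#'
#' Captures everything needed to reproduce a run: configuration snapshot
#' hash, derived stage seeds, design sizes, package version and timestamp.
#' Re-running with an identical manifest reproduces all seeded stages.
#'
#' @param config A `cea_config`.
#' @param n Cohort size (metadata).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, n = NA_integer_) {
  structure(list(
    package_version = as.character(utils::packageVersion("trialcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = rlang::hash(config[setdiff(names(config),
                                             c("value_set", "crosswalk"))]),
    country = config$country, n = n, m = config$m, B = config$B,
    n_draws = config$n_draws,
    seeds = list(master = config$seed,
                 imputation = config$imputation$seed,
                 simulation = config$sim$seed,
                 bootstrap = child_seed(config$seed, 4)),
    scenario = config$sim$scenario,
    discount_rate = config$costing$discount_rate),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

## ---- command-line entry point ----------------------------------------------

#' Command-line entry point
#'
#' Dispatches the pipeline stages from a character vector of arguments (as
#' a thin Rscript wrapper would pass). Subcommands: `generate` (write a
#' synthetic cohort), `validate` (schema report), `impute` (write imputed
#' tables), `within-trial` (per-patient results), `extrapolate` (per-draw
#' post-trial means), `cea` / `all` (full analysis: Table-1-style CSV,
#' CE-plane CSV, CEAC CSV, summary JSON, manifest), `scenarios`
#' (sensitivity/subgroup grid). Options: `--config` (YAML overrides),
#' `--seed`, `--out-dir`, `--data-dir`, `--country`, `--scenario`, `--m`,
#' `--replicates`, `--draws`, `--n`.
#'
#' @param args Character vector of command-line arguments; the first
#'   element is the subcommand.
#' @return Exit status (0 on success), invisibly; artifacts are written to
#'   `--out-dir`.
#' @export
cli_run <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: trialcea <generate|validate|impute|within-trial|",
            "extrapolate|cea|scenarios|all> [options]")
    return(invisible(1L))
  }
  sub <- args[1]
  opts <- tryCatch(parse_cli_options(args[-1]),
                   error = function(e) e)
  if (inherits(opts, "error")) {
    message("argument error: ", conditionMessage(opts))
    return(invisible(1L))
  }
  status <- tryCatch({
    dispatch_cli(sub, opts)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_options <- function(args) {
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-dir", dest = "out_dir", type = "character",
                          default = "trialcea_out"),
    optparse::make_option("--data-dir", dest = "data_dir",
                          type = "character", default = NULL),
    optparse::make_option("--country", type = "character", default = "US"),
    optparse::make_option("--scenario", type = "character",
                          default = "base"),
    optparse::make_option("--m", type = "integer", default = 28L),
    optparse::make_option("--replicates", type = "integer", default = 800L),
    optparse::make_option("--draws", type = "integer", default = 800L),
    optparse::make_option("--n", type = "integer", default = 2000L))
  parser <- optparse::OptionParser(option_list = spec)
  opts <- optparse::parse_args(parser, args = args)
  if (!opts$country %in% c("US", "UK")) {
    abort("invalid value for option `country`: must be US or UK")
  }
  if (!is.null(opts$config)) {
    ov <- yaml::read_yaml(opts$config)
    known <- c("n", "m", "replicates", "draws", "seed", "country",
               "scenario", "missing_utility_rate")
    bad <- setdiff(names(ov), known)
    if (length(bad)) {
      abort(paste0("invalid config key(s): ", paste(bad, collapse = ", ")))
    }
    for (k in intersect(names(ov), known)) opts[[k]] <- ov[[k]]
  }
  opts
}

cli_config <- function(opts) {
  cfg <- cea_config(country = opts$country, m = opts$m,
                    B = opts$replicates, n_draws = opts$draws,
                    seed = opts$seed)
  if (!opts$scenario %in% c("base", "scenario1", "scenario2")) {
    abort(paste0("invalid value for option `scenario`: ", opts$scenario))
  }
  cfg$sim$scenario <- opts$scenario
  cfg
}

cli_cohort <- function(opts) {
  if (!is.null(opts$data_dir)) {
    read_cohort(opts$data_dir)
  } else {
    gcfg <- cohort_config(
      n_patients = opts$n, seed = opts$seed,
      missing_utility_rate = opts$missing_utility_rate %||% 0.28)
    apply_missingness(generate_cohort(gcfg), gcfg)
  }
}

dispatch_cli <- function(sub, opts) {
  out <- opts$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- cli_config(opts)
  if (sub == "generate") {
    write_cohort(cli_cohort(opts), out)
    write_manifest(run_manifest(cfg, n = opts$n),
                   file.path(out, "manifest.json"))
    return(invisible(out))
  }
  cohort <- cli_cohort(opts)
  if (sub == "validate") {
    rep <- validate_tables(cohort)
    readr::write_csv(rep, file.path(out, "validation_report.csv"))
    if (nrow(rep)) abort(paste0(nrow(rep), " schema violation(s); see ",
                                file.path(out, "validation_report.csv")))
    return(invisible(out))
  }
  dataset <- impute_baseline(add_utility_values(cohort, cfg$value_set,
                                                cfg$crosswalk))
  if (sub %in% c("impute", "within-trial", "extrapolate")) {
    imps <- impute_chained(dataset, cfg$imputation)
    if (sub == "impute") {
      for (k in seq_len(imps$m)) {
        readr::write_csv(imps$utilities[[k]],
                         file.path(out, sprintf("imputed_utilities_%02d.csv", k)))
        readr::write_csv(imps$risk_factors[[k]],
                         file.path(out, sprintf("imputed_risk_factors_%02d.csv", k)))
      }
    } else if (sub == "within-trial") {
      pp <- within_trial_results(dataset, imps, cfg$costing)
      readr::write_csv(pp, file.path(out, "within_trial_per_patient.csv"))
    } else {
      rf_avg <- average_risk_factor_imputations(imps)
      profiles <- end_of_trial_profiles(dataset, risk_factors = rf_avg,
                                        utility_tables = imps$utilities)
      post <- simulate_cohort(profiles, cfg$equations, cfg$comp_table,
                              cfg$costing, cfg$sim,
                              covariance = cfg$coef_covariance)
      readr::write_csv(post, file.path(out, "post_trial_draws.csv"))
    }
    write_manifest(run_manifest(cfg, n = nrow(cohort$patients)),
                   file.path(out, "manifest.json"))
    return(invisible(out))
  }
  if (sub %in% c("cea", "all")) {
    res <- run_cea(cohort, cfg)
    readr::write_csv(res$table1, file.path(out, "table1.csv"))
    readr::write_csv(res$replicates, file.path(out, "ce_plane.csv"))
    readr::write_csv(res$ceac, file.path(out, "ceac.csv"))
    jsonlite::write_json(
      as.list(glance(res)), file.path(out, "summary.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    write_manifest(res$manifest, file.path(out, "manifest.json"))
    return(invisible(out))
  }
  if (sub == "scenarios") {
    res <- run_scenarios(cohort, cfg)
    readr::write_csv(res, file.path(out, "scenarios.csv"))
    write_manifest(run_manifest(cfg, n = nrow(cohort$patients)),
                   file.path(out, "manifest.json"))
    return(invisible(out))
  }
  abort(paste0("unknown subcommand: ", sub))
}
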