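## EQ-5D value sets, 5L->3L crosswalk, and profile valuation.
##
## Value sets ship as editable CSV coefficient tables. The packaged tables
## are synthetic illustrations with the structure of published tariffs
## (additive per-dimension decrements plus an any-level-3 term); official
## tariff coefficients are licensed and must be supplied by the user.

#' Read an EQ-5D-3L value set coefficient table
#'
#' The table maps dimension-level indicators to utility decrements. Schema:
#' columns `term` (one of [eq5d_dimensions()] or `any3`), `level` (2 or 3
#' for dimension terms, NA for `any3`), `decrement` (>= 0). Profile 11111
#' always values to exactly 1; the achievable floor is
#' `1 - sum(max decrements) - any3`.
#'
#' @param path CSV file path.
#' @return A tibble of class `eq5d_value_set` with attributes `instrument`
#'   and `floor`.
#' @export
read_value_set <- function(path) {
  vs <- readr::read_csv(path, show_col_types = FALSE)
  validate_value_set(vs)
}

validate_value_set <- function(vs) {
  vs <- tibble::as_tibble(vs)
  stopifnot(all(c("term", "level", "decrement") %in% names(vs)))
  dims <- eq5d_dimensions()
  bad <- setdiff(vs$term, c(dims, "any3"))
  if (length(bad)) abort(paste0("unknown value-set term(s): ",
                                paste(bad, collapse = ", ")))
  if (any(vs$decrement < 0)) abort("value-set decrements must be >= 0")
  dim_rows <- vs$term %in% dims
  if (any(!vs$level[dim_rows] %in% 2:3)) {
    abort("dimension terms must have level 2 or 3 (level 1 is the anchor)")
  }
  worst <- sum(purrr::map_dbl(dims, function(d) {
    max(c(0, vs$decrement[vs$term == d]))
  })) + sum(vs$decrement[vs$term == "any3"])
  structure(vs, class = c("eq5d_value_set", class(vs)),
            instrument = "EQ5D3L", floor = 1 - worst)
}

#' Packaged synthetic value sets and crosswalk
#'
#' Loads the CSV coefficient tables shipped with the package. These are
#' synthetic placeholder tariffs (marked `_synthetic` in their filenames):
#' they have realistic structure and magnitudes but are not the published
#' US or UK value sets, which users must supply themselves.
#'
#' @param country `"US"` or `"UK"`: which synthetic table to load.
#' @return For `default_value_set()`, an `eq5d_value_set`; for
#'   `default_crosswalk()`, a crosswalk tibble.
#' @export
default_value_set <- function(country = c("US", "UK")) {
  country <- match.arg(country)
  f <- sprintf("value_set_%s_synthetic.csv", tolower(country))
  read_value_set(system.file("extdata", f, package = "trialcea",
                             mustWork = TRUE))
}

#' @rdname default_value_set
#' @export
default_crosswalk <- function() {
  read_crosswalk(system.file("extdata", "crosswalk_5l_to_3l_synthetic.csv",
                             package = "trialcea", mustWork = TRUE))
}

#' Read a 5L-to-3L crosswalk table
#'
#' Deterministic per-dimension level map. Schema: columns `dimension`
#' (a dimension name or `"all"`), `from_level` (1..5), `to_level` (1..3).
#' The map must be total (every 5L level of every dimension resolvable) and
#' must send level 1 to level 1 so that 11111 values to 1.
#'
#' @param path CSV file path.
#' @return A tibble of class `eq5d_crosswalk`.
#' @export
read_crosswalk <- function(path) {
  cw <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("dimension", "from_level", "to_level") %in% names(cw)))
  dims <- eq5d_dimensions()
  for (d in dims) {
    sub <- cw[cw$dimension %in% c(d, "all"), ]
    if (!all(1:5 %in% sub$from_level)) {
      abort(paste0("crosswalk is not total for dimension ", d))
    }
  }
  if (any(cw$to_level[cw$from_level == 1] != 1)) {
    abort("crosswalk must map level 1 to level 1 (anchor preservation)")
  }
  if (any(!cw$to_level %in% 1:3)) abort("`to_level` must be in 1..3")
  structure(tibble::as_tibble(cw), class = c("eq5d_crosswalk", class(cw)))
}

crosswalk_levels <- function(levels_mat, crosswalk) {
  dims <- eq5d_dimensions()
  out <- levels_mat
  for (j in seq_along(dims)) {
    sub <- crosswalk[crosswalk$dimension %in% c(dims[j], "all"), ]
    # dimension-specific rows take precedence over "all"
    sub <- sub[order(sub$dimension == "all"), ]
    map <- sub$to_level[match(levels_mat[, j], sub$from_level)]
    out[, j] <- map
  }
  out
}

#' Value one EQ-5D profile
#'
#' Values a single profile under a 3L value set: 3L profiles are valued
#' directly; 5L profiles are first mapped level-by-level through the
#' crosswalk. Valuation is deterministic: utility =
#' 1 - sum of dimension-level decrements - any-level-3 decrement (if any
#' dimension is at level 3).
#'
#' @param profile Integer vector of 5 levels, or a string like `"21111"`.
#' @param instrument `"EQ5D3L"` or `"EQ5D5L"`.
#' @param value_set An `eq5d_value_set`.
#' @param crosswalk An `eq5d_crosswalk`; required for 5L profiles.
#' @return A single utility value (<= 1; >= the value-set floor).
#' @export
#' @examples
#' vs <- default_value_set("US")
#' value_profile("11111", "EQ5D3L", vs)   # anchor: exactly 1
value_profile <- function(profile, instrument = c("EQ5D3L", "EQ5D5L"),
                          value_set, crosswalk = NULL) {
  instrument <- match.arg(instrument)
  if (is.character(profile)) {
    profile <- as.integer(strsplit(profile, "")[[1]])
  }
  if (length(profile) != 5 || anyNA(profile)) {
    abort("`profile` must give 5 levels")
  }
  top <- if (instrument == "EQ5D5L") 5L else 3L
  if (any(profile < 1 | profile > top)) {
    abort(paste0("levels out of range 1..", top, " for ", instrument))
  }
  m <- matrix(profile, nrow = 1)
  if (instrument == "EQ5D5L") {
    if (is.null(crosswalk)) abort("5L profiles require a crosswalk")
    m <- crosswalk_levels(m, crosswalk)
  }
  value_levels(m, value_set)[1]
}

# vectorized valuation of a matrix of 3L levels (rows = profiles)
value_levels <- function(levels_mat, value_set) {
  dims <- eq5d_dimensions()
  u <- rep(1, nrow(levels_mat))
  for (j in seq_along(dims)) {
    for (lv in 2:3) {
      dec <- value_set$decrement[value_set$term == dims[j] &
                                   value_set$level == lv]
      if (length(dec)) u <- u - dec * (levels_mat[, j] == lv)
    }
  }
  any3 <- value_set$decrement[value_set$term == "any3"]
  if (length(any3)) u <- u - any3 * (rowSums(levels_mat == 3) > 0)
  u
}

#' Value all EQ-5D responses in a cohort utility table
#'
#' Adds a `utility` column to a cohort's `utilities` table by valuing every
#' complete profile (5L responses crosswalked first). Visits with missing
#' responses get `NA` utility. Stores the value-set floor in the cohort for
#' downstream range checks.
#'
#' @param cohort A `cea_cohort`.
#' @param value_set An `eq5d_value_set`.
#' @param crosswalk An `eq5d_crosswalk`.
#' @return The cohort with `utilities$utility` filled in.
#' @export
add_utility_values <- function(cohort, value_set, crosswalk = default_crosswalk()) {
  stop_if_not_cohort(cohort)
  ut <- cohort$utilities
  m <- as.matrix(ut[, eq5d_dimensions()])
  u <- rep(NA_real_, nrow(ut))
  ok <- stats::complete.cases(m)
  is5 <- ut$instrument == "EQ5D5L"
  if (any(ok & is5)) {
    m5 <- crosswalk_levels(m[ok & is5, , drop = FALSE], crosswalk)
    u[ok & is5] <- value_levels(m5, value_set)
  }
  if (any(ok & !is5)) {
    u[ok & !is5] <- value_levels(m[ok & !is5, , drop = FALSE], value_set)
  }
  ut$utility <- u
  cohort$utilities <- ut
  cohort$value_floor <- attr(value_set, "floor")
  cohort
}
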