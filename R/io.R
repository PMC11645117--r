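# CSV interchange with schema validation on read.

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s) %s", what, paste(missing, collapse = ", ")),
          class = "hcesfort_schema_error")
  }
}

check_vocab <- function(x, allowed, what, col) {
  bad <- which(!is.na(x) & !x %in% allowed)
  if (length(bad) > 0) {
    abort(sprintf("%s: column %s has invalid value '%s' (row %d)",
                  what, col, x[bad[1]], bad[1]),
          class = "hcesfort_schema_error")
  }
}

check_positive <- function(x, what, col, allow_na = TRUE) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: column %s must be positive (row %d has %s)",
                  what, col, bad[1], x[bad[1]]),
          class = "hcesfort_schema_error")
  }
  if (!allow_na && any(is.na(x))) {
    abort(sprintf("%s: column %s has missing values", what, col),
          class = "hcesfort_schema_error")
  }
}

read_csv_quiet <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "hcesfort_config_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and validate a consumption table
#'
#' @param path CSV with `household_id`, `food_code`, `quantity`, `unit`,
#'   `source`. Units and sources come from closed vocabularies; quantities
#'   must be positive or empty (missing).
#' @return Validated tibble.
#' @export
read_consumption <- function(path) {
  df <- read_csv_quiet(path)
  check_columns(df, c("household_id", "food_code", "quantity", "unit", "source"),
                "consumption")
  check_vocab(df$unit, VALID_UNITS, "consumption", "unit")
  check_vocab(df$source, VALID_SOURCES, "consumption", "source")
  check_positive(df$quantity, "consumption", "quantity")
  df
}

#' Read and validate a household roster
#'
#' @param path CSV with `household_id`, `member_id`, `age_years`,
#'   `age_months`, `sex`, `weight_kg`, `mother_id`.
#' @return Validated tibble.
#' @export
read_roster <- function(path) {
  df <- read_csv_quiet(path)
  check_columns(df, c("household_id", "member_id", "age_years", "age_months",
                      "sex", "weight_kg", "mother_id"), "roster")
  check_vocab(df$sex, c("male", "female"), "roster", "sex")
  age <- ifelse(!is.na(df$age_months), df$age_months / 12, df$age_years)
  if (any(is.na(age)) || any(age < 0)) {
    abort("roster: every member needs a non-negative age", class = "hcesfort_schema_error")
  }
  df
}

#' Read and validate the household design table
#'
#' @param path CSV with `household_id`, `stratum`, `cluster`, `urban`,
#'   `weight` (positive survey weights).
#' @return Validated tibble.
#' @export
read_households <- function(path) {
  df <- read_csv_quiet(path)
  check_columns(df, c("household_id", "stratum", "cluster", "urban", "weight"),
                "households")
  check_positive(df$weight, "households", "weight", allow_na = FALSE)
  df
}

#' Read and validate a food composition table
#'
#' @param path CSV with `food_code` plus the nutrient columns of
#'   [nutrient_columns()] (non-negative, per 100 g edible portion).
#' @return Validated tibble.
#' @export
read_fct <- function(path) {
  df <- read_csv_quiet(path)
  check_columns(df, c("food_code", nutrient_columns()), "fct")
  for (nm in nutrient_columns()) {
    bad <- which(!is.na(df[[nm]]) & df[[nm]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("fct: %s negative in row %d", nm, bad[1]),
            class = "hcesfort_schema_error")
    }
  }
  df
}

#' Write the synthetic survey and fixture tables to a directory
#'
#' Writes `roster.csv`, `consumption.csv`, `households.csv`, `fct.csv`,
#' `recipes.csv`, `portions.csv`, `refuse_density.csv` and `weights.csv`
#' (component frequency weights).
#'
#' @param survey Result of [generate_survey()].
#' @param fixtures Result of [generate_fixtures()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_tables <- function(survey, fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(survey$roster, file.path(dir, "roster.csv"))
  readr::write_csv(survey$consumption, file.path(dir, "consumption.csv"))
  readr::write_csv(survey$households, file.path(dir, "households.csv"))
  readr::write_csv(fixtures$fct, file.path(dir, "fct.csv"))
  readr::write_csv(fixtures$recipes, file.path(dir, "recipes.csv"))
  readr::write_csv(fixtures$portions, file.path(dir, "portions.csv"))
  readr::write_csv(fixtures$refuse_density, file.path(dir, "refuse_density.csv"))
  readr::write_csv(fixtures$hbs_weights, file.path(dir, "weights.csv"))
  invisible(dir)
}

#' Read pipeline input tables from a directory
#'
#' Counterpart of [write_survey_tables()]: reads and validates the survey
#' tables and reassembles a fixture list.
#'
#' @param dir Directory holding the CSV tables.
#' @return List with `consumption`, `roster`, `households` and `fixtures`.
#' @export
read_survey_tables <- function(dir) {
  fixtures <- list(
    fct = read_fct(file.path(dir, "fct.csv")),
    recipes = read_csv_quiet(file.path(dir, "recipes.csv")),
    portions = read_csv_quiet(file.path(dir, "portions.csv")),
    refuse_density = read_csv_quiet(file.path(dir, "refuse_density.csv")),
    hbs_weights = read_csv_quiet(file.path(dir, "weights.csv")),
    food_list = default_food_list()
  )
  list(consumption = read_consumption(file.path(dir, "consumption.csv")),
       roster = read_roster(file.path(dir, "roster.csv")),
       households = read_households(file.path(dir, "households.csv")),
       fixtures = fixtures)
}
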