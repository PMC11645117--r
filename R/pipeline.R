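#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a directory of input
#' CSV tables (see [read_survey_tables()]) or `simulate = TRUE` to generate
#' a synthetic survey, plus scenario list, parameter tables and flags.
#'
#' @param simulate Generate a synthetic survey instead of reading tables.
#' @param input_dir Directory of input CSVs when `simulate = FALSE`.
#' @param design,model Synthetic design/model when simulating.
#' @param scenarios Scenarios to run (default all four).
#' @param fortification_spec Fortification parameter table.
#' @param thresholds Requirement/upper-limit thresholds.
#' @param iron_curve Iron risk curve.
#' @param eer_table Energy requirement table.
#' @param seed Seed for the simulation.
#' @param outdir Optional output directory for result CSVs.
#' @param purchased_only Count only purchased vehicle quantities as
#'   fortifiable.
#' @param weighted Use survey weights in summaries.
#' @return A `hcesfort_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, input_dir = NULL,
                            design = survey_design(),
                            model = default_consumption_model(),
                            scenarios = scenario_names(),
                            fortification_spec = default_fortification_spec(),
                            thresholds = default_thresholds(),
                            iron_curve = default_iron_risk_curve(),
                            eer_table = default_eer_table(),
                            seed = 1L, outdir = NULL,
                            purchased_only = FALSE, weighted = TRUE) {
  bad <- setdiff(scenarios, SCENARIOS)
  if (length(bad) > 0) {
    abort(sprintf("unknown scenario(s): %s", paste(bad, collapse = ", ")),
          class = "hcesfort_config_error")
  }
  if (!simulate && is.null(input_dir)) {
    abort("input_dir is required when simulate = FALSE", class = "hcesfort_config_error")
  }
  structure(list(simulate = simulate, input_dir = input_dir, design = design,
                 model = model, scenarios = scenarios,
                 fortification_spec = fortification_spec,
                 thresholds = thresholds, iron_curve = iron_curve,
                 eer_table = eer_table, seed = seed, outdir = outdir,
                 purchased_only = purchased_only, weighted = weighted),
            class = "hcesfort_config")
}

#' Run the full pipeline
#'
#' Chains the stages end to end: obtain the survey (simulate or read),
#' convert and clean quantities, compute vehicle equivalents and household
#' nutrient supplies, standardise by adult female equivalents, apply the
#' fortification scenarios, and produce survey-weighted stratified
#' summaries. Deterministic given the seed.
#'
#' @param config Configuration from [pipeline_config()].
#' @return List with `households`, `roster`, `cleaned`, `vehicles`,
#'   `supply`, `afe`, `base_intakes`, `scenario_intakes`, `summaries`,
#'   `survey` (when simulated) and a `log` list (seed, counts, exclusions).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "hcesfort_config")) {
    abort("config must come from pipeline_config()", class = "hcesfort_config_error")
  }
  fixtures <- if (config$simulate) generate_fixtures(config$seed) else NULL

  if (config$simulate) {
    survey <- generate_survey(config$design, config$model, fixtures,
                              seed = config$seed,
                              fortification_spec = config$fortification_spec,
                              thresholds = config$thresholds)
    consumption <- survey$consumption
    roster <- survey$roster
    households <- survey$households
  } else {
    tabs <- read_survey_tables(config$input_dir)
    survey <- NULL
    consumption <- tabs$consumption
    roster <- tabs$roster
    households <- tabs$households
    fixtures <- tabs$fixtures
  }

  n_total <- length(unique(households$household_id))
  afe <- household_afe(roster, config$eer_table)
  cleaned <- prepare_quantities(consumption, fixtures, households, afe)
  n_analysed <- length(unique(cleaned$household_id))

  veh_input <- if (config$purchased_only) {
    cleaned[cleaned$source == "purchase", ]
  } else {
    cleaned
  }
  veh <- vehicle_equivalents(veh_input, fixtures$recipes, fixtures$food_list)
  supply <- household_nutrient_supply(cleaned, fixtures$fct)
  base_intakes <- intake_per_afe(supply, afe)
  scen <- apply_scenarios(veh, base_intakes, config$fortification_spec,
                          config$scenarios)
  summaries <- stratified_summaries(scen, veh, households,
                                    thresholds = config$thresholds,
                                    iron_curve = config$iron_curve,
                                    weighted = config$weighted)

  log <- list(seed = config$seed,
              n_households = n_total,
              n_analysed = n_analysed,
              n_excluded_no_food = n_total - n_analysed,
              n_outliers_replaced = sum(cleaned$was_outlier),
              n_missing_imputed = sum(cleaned$was_imputed),
              scenarios = config$scenarios,
              package_version = as.character(utils::packageVersion("hcesfort")))

  out <- list(households = households, roster = roster, cleaned = cleaned,
              vehicles = veh, supply = supply, afe = afe,
              base_intakes = base_intakes, scenario_intakes = scen,
              summaries = summaries, survey = survey, log = log)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(summaries$coverage, file.path(config$outdir, "coverage.csv"))
    readr::write_csv(summaries$consumption, file.path(config$outdir, "intake_summaries.csv"))
    readr::write_csv(summaries$inadequacy, file.path(config$outdir, "inadequacy.csv"))
    readr::write_csv(summaries$excess, file.path(config$outdir, "excess.csv"))
    readr::write_csv(summaries$gaps, file.path(config$outdir, "gaps.csv"))
    readr::write_csv(scen, file.path(config$outdir, "scenario_intakes.csv"))
    readr::write_csv(veh, file.path(config$outdir, "vehicle_equivalents.csv"))
    readr::write_csv(cleaned, file.path(config$outdir, "cleaned_quantities.csv"))
    readr::write_csv(afe, file.path(config$outdir, "household_afe.csv"))
    writeLines(paste(names(log), vapply(log, function(x) paste(x, collapse = ","),
                                        character(1)), sep = "="),
               file.path(config$outdir, "run_log.txt"))
  }
  out
}
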