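#' Generate reference fixture tables for the synthetic survey
#'
#' Builds the full set of reference tables the pipeline needs: a food
#' composition table (per-100 g edible portion) covering every item of the
#' 60-item food list, recipe ingredient fractions for processed wheat-flour /
#' oil products, portion masses for items reported in `pieces`, refuse
#' fractions and densities, and the frequency weights used to average the
#' components of concatenated items. Composite rows of the composition table
#' are computed with [composite_composition()] from the component entries.
#'
#' The tables are deterministic reference data; `seed` is accepted for
#' interface symmetry with [generate_survey()] and reserved for future
#' randomised fixture variants.
#'
#' @param seed Integer; unused by the default deterministic tables.
#' @return A list of tibbles: `fct`, `recipes`, `portions`, `refuse_density`,
#'   `hbs_weights`, `components` and `food_list`.
#' @export
generate_fixtures <- function(seed = 1L) {
  master <- master_food_table()
  comps <- composite_components_table()

  nutr <- nutrient_columns()
  fct <- master[, c("food_code", nutr, "source_fct")]

  # fill the two concatenated items from their components
  for (code in unique(comps$composite_code)) {
    cc <- comps[comps$composite_code == code, ]
    entry <- composite_composition(cc[, nutr], cc$hbs_weight)
    fct[fct$food_code == code, nutr] <- entry
    fct$source_fct[fct$food_code == code] <-
      paste0("composite(", paste(cc$component, collapse = ", "), ")")
  }

  portions <- master[!is.na(master$portion_g), c("food_code", "portion_g")]
  refuse_density <- master[, c("food_code", "refuse_fraction", "density_g_ml")]
  hbs_weights <- comps[, c("composite_code", "component", "hbs_weight")]
  # frequency weights are stored normalised to sum to one per composite
  hbs_weights <- dplyr::mutate(
    dplyr::group_by(hbs_weights, .data$composite_code),
    hbs_weight = .data$hbs_weight / sum(.data$hbs_weight)
  )
  hbs_weights <- dplyr::ungroup(hbs_weights)

  list(
    fct = tibble::as_tibble(fct),
    recipes = default_recipe_table(),
    portions = tibble::as_tibble(portions),
    refuse_density = tibble::as_tibble(refuse_density),
    hbs_weights = hbs_weights,
    components = comps,
    food_list = default_food_list()
  )
}
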