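# shared small fixtures for the suite

fx <- generate_fixtures()

single_stratum_design <- function(clusters = 5, hpc = 8) {
  survey_design(
    clusters_per_stratum = c("Dar es Salaam" = clusters),
    households_per_cluster = hpc,
    pop_share = c("Dar es Salaam" = 1),
    urban_share = c("Dar es Salaam" = 1)
  )
}

small_design <- function() {
  survey_design(clusters_per_stratum = c("Dar es Salaam" = 4,
                                         "Mainland other urban" = 4,
                                         "Mainland rural" = 8,
                                         "Zanzibar" = 3))
}

# n = 1000 households across the four strata
mid_design <- function() {
  survey_design(clusters_per_stratum = c("Dar es Salaam" = 20,
                                         "Mainland other urban" = 20,
                                         "Mainland rural" = 68,
                                         "Zanzibar" = 17))
}

single_stratum_model <- function(...) {
  default_consumption_model(strata = "Dar es Salaam", ...)
}

reference_woman <- function(household_id = 1, member_id = 1, weight = 56) {
  tibble::tibble(household_id = household_id, member_id = member_id,
                 age_years = 25, age_months = NA_real_, sex = "female",
                 weight_kg = weight, mother_id = NA_integer_)
}

member_row <- function(household_id, member_id, age_years = NA, age_months = NA,
                       sex = "female", weight_kg = NA, mother_id = NA) {
  tibble::tibble(household_id = household_id, member_id = member_id,
                 age_years = as.numeric(age_years),
                 age_months = as.numeric(age_months), sex = sex,
                 weight_kg = as.numeric(weight_kg),
                 mother_id = as.integer(mother_id))
}

cleaned_row <- function(household_id, food_code, grams) {
  tibble::tibble(household_id = household_id, food_code = as.integer(food_code),
                 source = "purchase", grams_per_day = grams,
                 was_outlier = FALSE, was_imputed = FALSE,
                 edible_grams_per_day = grams)
}
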