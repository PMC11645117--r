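#' Default energy requirement table
#'
#' Configurable description of how each household member's estimated energy
#' requirement (EER, kcal/d) is computed, used to express households in adult
#' female equivalents (AFE). The default encodes:
#'
#' * basal metabolic rate as an affine function of body weight per age-sex
#'   band (Schofield coefficients, kcal/d), multiplied by a physical activity
#'   level of 1.85 ("active or moderately active");
#' * children below 24 months contribute the energy needed from
#'   complementary (non-breastmilk) foods directly: 0, 76, 269, 451 and
#'   746 kcal/d for ages 0-2, 3-5, 6-8, 9-11 and 12-23 months;
#' * lactating women (identified via mother links, see
#'   [identify_lactating()]) add 500 kcal/d;
#' * body-weight fallbacks for bands without measured weights: adult men use
#'   a global-database weight, 16- and 17-year-old males interpolate at two
#'   midpoints between the 15-year-old survey mean and the adult value, and
#'   women above 50 use the survey mean of measured women aged 19-49;
#' * the reference requirement is that of a non-pregnant, non-lactating
#'   woman aged 18-29.9 years at the female 19-49 mean weight.
#'
#' Every element can be overridden to audit or swap the requirement basis.
#'
#' @param pal Physical activity level multiplier applied to BMR.
#' @param lactation_bonus_kcal Additional kcal/d for lactating women.
#' @param adult_male_kg Fallback weight for males 18+ (global database value).
#' @param fallback_female_kg Fallback reference female weight when the roster
#'   holds no measured women aged 19-49.
#' @return A list with elements `pal`, `schofield`, `complementary_kcal`,
#'   `lactation_bonus_kcal`, `weight_fallbacks` and `reference`.
#' @export
default_eer_table <- function(pal = 1.85, lactation_bonus_kcal = 500,
                              adult_male_kg = 61, fallback_female_kg = 56) {
  schofield <- tibble::tribble(
    ~sex, ~age_min, ~age_max, ~a, ~b,
    "male",   2,  3,  59.512,  -30.4,
    "male",   3, 10,  22.706,  504.3,
    "male",  10, 18,  17.686,  658.2,
    "male",  18, 30,  15.057,  692.2,
    "male",  30, 60,  11.472,  873.1,
    "male",  60, Inf, 11.711,  587.7,
    "female", 2,  3,  58.317,  -31.1,
    "female", 3, 10,  20.315,  485.9,
    "female",10, 18,  13.384,  692.6,
    "female",18, 30,  14.818,  486.6,
    "female",30, 60,   8.126,  845.6,
    "female",60, Inf,  9.082,  658.5
  )
  complementary <- tibble::tribble(
    ~age_min_months, ~age_max_months, ~kcal,
    0,  3,   0,
    3,  6,   76,
    6,  9,   269,
    9,  12,  451,
    12, 24,  746
  )
  list(
    pal = pal,
    schofield = schofield,
    complementary_kcal = complementary,
    lactation_bonus_kcal = lactation_bonus_kcal,
    weight_fallbacks = list(
      adult_male_kg = adult_male_kg,
      fallback_female_kg = fallback_female_kg,
      fallback_male15_kg = 50
    ),
    reference = list(sex = "female", age_min = 18, age_max = 30)
  )
}

# age in years for every member, combining the months column used below 24
# months with the years column used elsewhere
member_age_years <- function(roster) {
  ifelse(!is.na(roster$age_months), roster$age_months / 12, roster$age_years)
}

#' Flag lactating women via mother-child links
#'
#' A woman is assumed lactating if she is recorded as the biological mother
#' (`mother_id` link on the child's row) of a household member below 24
#' months of age. Surveys of this type carry no direct lactation or pregnancy
#' status, so this proxy is the identification rule.
#'
#' @param roster Member table with `household_id`, `member_id`, `sex`,
#'   `age_years`, `age_months` and `mother_id` columns.
#' @return `roster` with a logical `is_lactating` column added.
#' @export
identify_lactating <- function(roster) {
  age_y <- member_age_years(roster)
  infants <- roster[!is.na(age_y) & age_y < 2, c("household_id", "mother_id")]
  infants <- infants[!is.na(infants$mother_id), ]
  key <- paste(roster$household_id, roster$member_id)
  flag <- key %in% paste(infants$household_id, infants$mother_id)
  roster$is_lactating <- flag & roster$sex == "female"
  roster
}

#' Resolve body weights for energy requirement calculation
#'
#' Measured weights are kept as-is. Missing weights are resolved with the
#' fallback rules of the requirement table: adult males (18+) use the
#' global-database weight; males aged 16 and 17 are set at the two midpoints
#' between the survey mean of measured 15-year-old males and the adult male
#' value; females above 50 use the survey mean of measured females aged
#' 19-49. Any weight still missing falls back to the sex-specific reference
#' value.
#'
#' @param roster Member table (see [identify_lactating()]) with `weight_kg`.
#' @param eer_table Requirement table from [default_eer_table()].
#' @return `roster` with a `weight_resolved_kg` column.
#' @export
resolve_weights <- function(roster, eer_table = default_eer_table()) {
  fb <- eer_table$weight_fallbacks
  age <- member_age_years(roster)
  w <- roster$weight_kg

  measured_f <- roster$sex == "female" & !is.na(w) & age >= 19 & age < 50
  mean_f_19_49 <- if (any(measured_f)) mean(w[measured_f]) else fb$fallback_female_kg
  measured_m15 <- roster$sex == "male" & !is.na(w) & age >= 15 & age < 16
  w_m15 <- if (any(measured_m15)) mean(w[measured_m15]) else fb$fallback_male15_kg
  w_m18 <- fb$adult_male_kg
  w_m16 <- w_m15 + (w_m18 - w_m15) / 3
  w_m17 <- w_m15 + 2 * (w_m18 - w_m15) / 3

  out <- w
  miss <- is.na(w)
  male <- roster$sex == "male"
  out[miss & male & age >= 18] <- w_m18
  out[miss & male & age >= 16 & age < 17] <- w_m16
  out[miss & male & age >= 17 & age < 18] <- w_m17
  out[miss & !male & age >= 50] <- mean_f_19_49
  # residual gaps (not expected in well-formed rosters)
  still <- is.na(out)
  out[still & male] <- fb$adult_male_kg
  out[still & !male] <- fb$fallback_female_kg
  roster$weight_resolved_kg <- out
  roster
}

schofield_bmr <- function(age_y, sex, weight_kg, schofield) {
  bmr <- rep(NA_real_, length(age_y))
  for (i in seq_len(nrow(schofield))) {
    row <- schofield[i, ]
    sel <- sex == row$sex & age_y >= row$age_min & age_y < row$age_max
    bmr[sel] <- row$a * weight_kg[sel] + row$b
  }
  bmr
}

#' Reference energy requirement (kcal/d)
#'
#' EER of a non-pregnant, non-lactating woman aged 18-29.9 years at the
#' reference weight: the mean measured weight of women aged 19-49 in the
#' roster when available, otherwise the table's fallback.
#'
#' @param eer_table Requirement table from [default_eer_table()].
#' @param roster Optional member table used to derive the reference weight.
#' @return Reference EER in kcal/d.
#' @export
reference_eer <- function(eer_table = default_eer_table(), roster = NULL) {
  fb <- eer_table$weight_fallbacks
  w <- fb$fallback_female_kg
  if (!is.null(roster)) {
    age <- member_age_years(roster)
    sel <- roster$sex == "female" & !is.na(roster$weight_kg) &
      age >= 19 & age < 50
    if (any(sel)) w <- mean(roster$weight_kg[sel])
  }
  ref <- eer_table$reference
  sch <- eer_table$schofield
  band <- sch[sch$sex == ref$sex & sch$age_min == ref$age_min, ]
  (band$a[1] * w + band$b[1]) * eer_table$pal
}

#' Estimated energy requirement per member (kcal/d)
#'
#' Children below 24 months contribute the complementary-food energy for
#' their age band; everyone else contributes Schofield BMR at the resolved
#' body weight times the physical activity level; lactating women add the
#' lactation bonus.
#'
#' @param roster Member table; `is_lactating` and `weight_resolved_kg` are
#'   computed on the fly when absent.
#' @inheritParams resolve_weights
#' @return `roster` with an `eer_kcal` column.
#' @export
member_eer <- function(roster, eer_table = default_eer_table()) {
  if (!"is_lactating" %in% names(roster)) roster <- identify_lactating(roster)
  if (!"weight_resolved_kg" %in% names(roster)) roster <- resolve_weights(roster, eer_table)
  age <- member_age_years(roster)
  if (any(is.na(age)) || any(age < 0)) {
    abort("every roster member needs a non-negative age", class = "hcesfort_config_error")
  }
  eer <- rep(NA_real_, nrow(roster))

  infant <- age < 2
  if (any(infant)) {
    months <- ifelse(is.na(roster$age_months), age * 12, roster$age_months)
    comp <- eer_table$complementary_kcal
    for (i in seq_len(nrow(comp))) {
      sel <- infant & months >= comp$age_min_months[i] & months < comp$age_max_months[i]
      eer[sel] <- comp$kcal[i]
    }
  }
  older <- !infant
  eer[older] <- schofield_bmr(age[older], roster$sex[older],
                              roster$weight_resolved_kg[older],
                              eer_table$schofield) * eer_table$pal
  if (any(is.na(eer))) {
    abort("age band not covered by the energy requirement table",
          class = "hcesfort_config_error")
  }
  eer <- pmax(eer, 0)
  eer[roster$is_lactating] <- eer[roster$is_lactating] + eer_table$lactation_bonus_kcal
  roster$eer_kcal <- eer
  roster
}

#' Household adult female equivalents
#'
#' Sums member energy requirements and divides by the reference requirement
#' of a non-pregnant, non-lactating woman aged 18-29.9 years. Households
#' whose members all contribute zero energy requirement (e.g. a lone
#' 1-month-old) are dropped with a warning, as they cannot standardise
#' intakes.
#'
#' @inheritParams member_eer
#' @return Tibble with `household_id` and `afe`.
#' @export
household_afe <- function(roster, eer_table = default_eer_table()) {
  if (nrow(roster) == 0) abort("empty roster")
  roster <- member_eer(roster, eer_table)
  ref <- reference_eer(eer_table, roster)
  out <- dplyr::summarise(dplyr::group_by(roster, .data$household_id),
                          afe = sum(.data$eer_kcal) / .env$ref, .groups = "drop")
  zero <- out$afe <= 0
  if (any(zero)) {
    warn(sprintf("%d household(s) with zero total energy requirement excluded", sum(zero)))
    out <- out[!zero, ]
  }
  out
}

#' Standardise nutrient supplies to per-AFE per-day intakes
#'
#' @param supply Tibble with `household_id` and nutrient columns
#'   ([nutrient_columns()]), in units per day.
#' @param hh_afe Tibble from [household_afe()].
#' @return Tibble with `household_id`, `afe` and nutrient columns divided by
#'   the household AFE (units per day per AFE). Households absent from
#'   `hh_afe` (zero AFE) are dropped.
#' @export
intake_per_afe <- function(supply, hh_afe) {
  stopifnot(all(hh_afe$afe > 0))
  joined <- dplyr::inner_join(supply, hh_afe, by = "household_id")
  nutr <- intersect(nutrient_columns(), names(joined))
  joined[nutr] <- joined[nutr] / joined$afe
  dplyr::relocate(joined, "household_id", "afe")
}
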