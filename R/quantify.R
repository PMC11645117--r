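#' Convert reported quantities to grams
#'
#' Applies the metric conversion for each reporting unit: `kg` x1000, `g`
#' as-is, `L`/`mL` via the item's density (g/mL), `pieces` via the item's
#' portion mass. Missing quantities propagate as `NA` grams (flagged and
#' imputed later by [clean_quantities()]).
#'
#' @param quantity Numeric vector of reported quantities (may contain `NA`).
#' @param unit Character vector of units, one of `kg`, `g`, `L`, `mL`,
#'   `pieces`.
#' @param food_code Integer vector of food codes (used to look up portion
#'   mass and density, and to name offenders in errors).
#' @param portions Portion table (`food_code`, `portion_g`).
#' @param refuse_density Refuse/density table (`food_code`,
#'   `refuse_fraction`, `density_g_ml`).
#' @return Numeric vector of grams over the recall period.
#' @export
to_grams <- function(quantity, unit, food_code, portions, refuse_density) {
  bad_unit <- !unit %in% VALID_UNITS
  if (any(bad_unit)) {
    abort(sprintf("unknown unit(s): %s", paste(unique(unit[bad_unit]), collapse = ", ")),
          class = "hcesfort_unit_error")
  }
  if (any(!is.na(quantity) & quantity <= 0)) {
    abort("reported quantities must be positive (use NA for missing)",
          class = "hcesfort_validation_error")
  }
  portion <- portions$portion_g[match(food_code, portions$food_code)]
  density <- refuse_density$density_g_ml[match(food_code, refuse_density$food_code)]

  need_portion <- unit == "pieces" & is.na(portion)
  if (any(need_portion)) {
    abort(sprintf("no portion mass for food code(s) reported in pieces: %s",
                  paste(unique(food_code[need_portion]), collapse = ", ")),
          class = "hcesfort_unit_error")
  }
  need_density <- unit %in% c("L", "mL") & is.na(density)
  if (any(need_density)) {
    abort(sprintf("no density for food code(s) reported in volume units: %s",
                  paste(unique(food_code[need_density]), collapse = ", ")),
          class = "hcesfort_unit_error")
  }
  dplyr::case_when(
    unit == "kg" ~ quantity * 1000,
    unit == "g" ~ quantity,
    unit == "L" ~ quantity * 1000 * density,
    unit == "mL" ~ quantity * density,
    unit == "pieces" ~ quantity * portion
  )
}

#' Edible grams after refuse subtraction
#'
#' @param grams Gram quantities as consumed.
#' @param refuse_fraction Non-edible fraction in `[0, 1)` (e.g. banana skin).
#' @return `grams * (1 - refuse_fraction)`.
#' @export
edible_grams <- function(grams, refuse_fraction) {
  if (any(refuse_fraction < 0 | refuse_fraction >= 1, na.rm = TRUE)) {
    abort("refuse_fraction must lie in [0, 1)", class = "hcesfort_domain_error")
  }
  grams * (1 - refuse_fraction)
}

#' Replace outlying and missing quantities by per-item consumer medians
#'
#' Quantities of each food item across its consuming households are
#' log-transformed; values whose log deviates from the median of logs by more
#' than 3 standard deviations (of the logs) are replaced by the untransformed
#' median quantity among consumers of that item, as are missing quantities.
#' Items require at least two non-missing consumers to define spread;
#' otherwise values pass through (missing values can still be imputed when
#' one consumer quantity exists). Items where every quantity is missing are
#' dropped with a warning.
#'
#' When the table carries a `stratum` column, detection and replacement are
#' performed per (food item, stratum): consumption levels of staples differ
#' so strongly between strata here that pooling nationally would flag the
#' legitimate lower tail of low-consumption strata.
#'
#' @param quantities Tibble with `household_id`, `food_code`, optionally
#'   `stratum`, and a numeric quantity column (`NA` = missing).
#' @param value_col Name of the quantity column (default `grams_per_day`).
#' @return The input with the quantity column cleaned plus logical
#'   `was_outlier` and `was_imputed` flags.
#' @export
clean_quantities <- function(quantities, value_col = "grams_per_day") {
  x <- quantities[[value_col]]
  if (any(!is.na(x) & x <= 0)) {
    abort("quantities must be positive or missing", class = "hcesfort_validation_error")
  }
  grp <- intersect(c("food_code", "stratum"), names(quantities))
  out <- dplyr::group_by(quantities, dplyr::across(dplyr::all_of(grp)))
  out <- dplyr::group_modify(out, function(df, key) {
    v <- df[[value_col]]
    obs <- !is.na(v)
    if (!any(obs)) {
      warn(sprintf("food code %s: all quantities missing; item dropped", key$food_code))
      return(df[0, , drop = FALSE])
    }
    med <- median(v[obs])
    outlier <- rep(FALSE, nrow(df))
    if (sum(obs) >= 2) {
      lg <- log(v[obs])
      s <- sd(lg)
      if (is.finite(s) && s > 0) {
        outlier[obs] <- abs(lg - median(lg)) > 3 * s
      }
    }
    imputed <- !obs
    v[outlier | imputed] <- med
    df[[value_col]] <- v
    df$was_outlier <- outlier
    df$was_imputed <- imputed
    df
  })
  out <- dplyr::ungroup(out)
  dplyr::relocate(out, "household_id", "food_code")
}

#' Frequency-weighted mean composition of a concatenated item
#'
#' Survey food lists concatenate several foods into one item (e.g. "onions,
#' tomatoes, carrots and green peppers"); its composition is the weighted
#' mean of the component entries, weighted by consumption frequency.
#'
#' @param components Data frame of component nutrient values (one row per
#'   component; any numeric columns).
#' @param weights Non-negative frequency weights, at least one positive.
#' @return A one-row tibble of weighted-mean values.
#' @export
composite_composition <- function(components, weights) {
  if (nrow(components) == 0) abort("empty component list")
  if (length(weights) != nrow(components)) abort("one weight per component required")
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  num <- vapply(components, is.numeric, logical(1))
  out <- components[1, , drop = FALSE]
  out[num] <- lapply(components[num], function(col) sum(w * col))
  tibble::as_tibble(out)
}

#' Per-household fortifiable vehicle consumption (grams/day)
#'
#' Vehicle equivalents are direct consumption of the vehicle item plus the
#' vehicle embedded in processed products via recipe mass fractions (bread,
#' buns/cakes/biscuits and sweets carry wheat flour and cooking oil).
#' Macaroni/spaghetti is deliberately excluded: its flour cannot be
#' attributed to domestic fortifiable milling. Maize flour has no recipe
#' products, so its equivalents equal direct consumption. Any other product
#' lacking a recipe is excluded with a warning.
#'
#' @param cleaned Cleaned quantity table with `household_id`, `food_code` and
#'   `edible_grams_per_day`.
#' @param recipes Recipe table (`product_code`, `ingredient`,
#'   `mass_fraction`).
#' @param food_list Food list from [default_food_list()].
#' @return Tibble with `household_id`, `cooking_oil`, `wheat_flour` and
#'   `maize_flour` columns in grams/day (0 for non-consumers).
#' @export
vehicle_equivalents <- function(cleaned, recipes, food_list = default_food_list()) {
  df <- dplyr::left_join(cleaned, food_list[, c("food_code", "vehicle", "product_code")],
                         by = "food_code")

  products <- unique(df$product_code[!is.na(df$product_code)])
  missing_recipe <- setdiff(products, c(recipes$product_code, "macaroni"))
  if (length(missing_recipe) > 0) {
    warn(sprintf("product(s) without recipe excluded from vehicle equivalents: %s",
                 paste(missing_recipe, collapse = ", ")))
  }

  direct <- dplyr::summarise(
    dplyr::group_by(df[!is.na(df$vehicle), ], .data$household_id, vehicle = .data$vehicle),
    grams = sum(.data$edible_grams_per_day), .groups = "drop"
  )
  via <- dplyr::inner_join(df[!is.na(df$product_code), ], recipes,
                           by = "product_code", relationship = "many-to-many")
  via <- dplyr::summarise(
    dplyr::group_by(via, .data$household_id, vehicle = .data$ingredient),
    grams = sum(.data$edible_grams_per_day * .data$mass_fraction), .groups = "drop"
  )
  all_v <- dplyr::bind_rows(direct, via)
  all_v <- dplyr::summarise(dplyr::group_by(all_v, .data$household_id, .data$vehicle),
                            grams = sum(.data$grams), .groups = "drop")
  wide <- tidyr::pivot_wider(all_v, names_from = "vehicle", values_from = "grams",
                             values_fill = 0)
  for (v in VEHICLES) if (is.null(wide[[v]])) wide[[v]] <- 0
  base <- tibble::tibble(household_id = unique(cleaned$household_id))
  out <- dplyr::left_join(base, wide[, c("household_id", VEHICLES)], by = "household_id")
  out[VEHICLES][is.na(out[VEHICLES])] <- 0
  out
}

#' Household daily nutrient supply from cleaned quantities
#'
#' Sums, over food items, edible grams/day divided by 100 times the per-100 g
#' composition value, per nutrient.
#'
#' @inheritParams vehicle_equivalents
#' @param fct Food composition table with `food_code` and the nutrient
#'   columns of [nutrient_columns()].
#' @return Tibble with `household_id` and nutrient totals per day.
#' @export
household_nutrient_supply <- function(cleaned, fct) {
  unmatched <- setdiff(unique(cleaned$food_code), fct$food_code)
  if (length(unmatched) > 0) {
    abort(sprintf("no composition match for food code(s): %s",
                  paste(sort(unmatched), collapse = ", ")),
          class = "hcesfort_match_error")
  }
  nutr <- nutrient_columns()
  df <- dplyr::inner_join(cleaned, fct[, c("food_code", nutr)], by = "food_code")
  df[nutr] <- df[nutr] * df$edible_grams_per_day / 100
  dplyr::summarise(dplyr::group_by(df, .data$household_id),
                   dplyr::across(dplyr::all_of(nutr), sum), .groups = "drop")
}

#' Convert, clean and refuse-adjust raw consumption records
#'
#' Chains the quantification steps: unit conversion to grams, division by
#' the recall period, the log-scale outlier/missingness cleaning rule, and
#' refuse subtraction. Households with no consumption rows at all are absent
#' from the output by construction (the analysable-sample exclusion rule).
#'
#' @param consumption Consumption records: `household_id`, `food_code`,
#'   `quantity`, `unit`, `source` (`NA` quantity = missing).
#' @param fixtures Fixture list from [generate_fixtures()] (uses `portions`
#'   and `refuse_density`).
#' @param households Optional design table with `household_id` and `stratum`;
#'   when given, the outlier rule runs per (food item, stratum).
#' @param hh_afe Optional AFE table from [household_afe()]. When given, the
#'   outlier rule operates on quantities standardised per AFE (the scale on
#'   which consumption is analysed and reported), so that household size
#'   does not masquerade as an outlying quantity; replacement medians are
#'   computed on that scale and mapped back to the household's quantity.
#'   Rows of households without a positive AFE are dropped.
#' @param recall_days Length of the recall period in days (default 7).
#' @return Cleaned quantity tibble with `grams_per_day`,
#'   `edible_grams_per_day`, `was_outlier` and `was_imputed`.
#' @export
prepare_quantities <- function(consumption, fixtures, households = NULL,
                               hh_afe = NULL, recall_days = 7) {
  grams <- to_grams(consumption$quantity, consumption$unit, consumption$food_code,
                    fixtures$portions, fixtures$refuse_density)
  q <- tibble::tibble(
    household_id = consumption$household_id,
    food_code = consumption$food_code,
    source = consumption$source,
    grams_per_day = grams / recall_days
  )
  if (!is.null(households)) {
    q$stratum <- households$stratum[match(q$household_id, households$household_id)]
  }
  afe <- rep(1, nrow(q))
  if (!is.null(hh_afe)) {
    afe <- hh_afe$afe[match(q$household_id, hh_afe$household_id)]
    if (any(is.na(afe))) {
      warn(sprintf("%d consumption row(s) of households without AFE dropped",
                   sum(is.na(afe))))
      q <- q[!is.na(afe), ]
      afe <- afe[!is.na(afe)]
    }
  }
  q$grams_per_day <- q$grams_per_day / afe
  cleaned <- clean_quantities(q)
  # map the per-AFE scale back to household quantities
  afe_back <- afe[match(paste(cleaned$household_id, cleaned$food_code),
                        paste(q$household_id, q$food_code))]
  cleaned$grams_per_day <- cleaned$grams_per_day * afe_back
  refuse <- fixtures$refuse_density$refuse_fraction[
    match(cleaned$food_code, fixtures$refuse_density$food_code)]
  cleaned$edible_grams_per_day <- edible_grams(cleaned$grams_per_day, refuse)
  cleaned
}
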