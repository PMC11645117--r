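#!/usr/bin/env Rscript
# Stage 2 - quantify food consumption.
#
# Reads the raw survey tables, converts reported quantities to edible
# grams/day (metric units, density for liquids, portion masses for pieces,
# refuse subtraction), applies the log-scale >3 SD outlier rule and
# missing-value imputation on the per-AFE scale, and derives per-household
# fortifiable vehicle equivalents (direct + recipe-embedded wheat flour and
# cooking oil; macaroni excluded).

library(hcesfort)

tabs <- read_survey_tables("results/survey")
afe <- household_afe(tabs$roster)
cleaned <- prepare_quantities(tabs$consumption, tabs$fixtures,
                              tabs$households, afe)
veh <- vehicle_equivalents(cleaned, tabs$fixtures$recipes,
                           tabs$fixtures$food_list)
supply <- household_nutrient_supply(cleaned, tabs$fixtures$fct)

readr::write_csv(cleaned, "results/cleaned_quantities.csv")
readr::write_csv(veh, "results/vehicle_equivalents.csv")
readr::write_csv(supply, "results/household_supply.csv")
readr::write_csv(afe, "results/household_afe.csv")

n_hh <- length(unique(tabs$households$household_id))
cat(sprintf("analysed %d of %d households (households with no food rows are excluded)\n",
            length(unique(cleaned$household_id)), n_hh))
cat(sprintf("replaced %d outliers and imputed %d missing quantities with consumer medians\n",
            sum(cleaned$was_outlier), sum(cleaned$was_imputed)))
cat(sprintf("vehicle consumers: oil %d, wheat flour %d, maize flour %d\n",
            sum(veh$cooking_oil > 0), sum(veh$wheat_flour > 0),
            sum(veh$maize_flour > 0)))
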