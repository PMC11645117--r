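#!/usr/bin/env Rscript
# Stage 3 - standardise household supplies per adult female equivalent.
#
# Household nutrient supplies are divided by the household's AFE: the sum of
# member energy requirements (PAL 1.85, complementary-food energy below 24
# months, +500 kcal/d for lactating women identified via mother links)
# relative to a non-pregnant, non-lactating woman aged 18-29.9 years.

library(hcesfort)

supply <- readr::read_csv("results/household_supply.csv", show_col_types = FALSE)
afe <- readr::read_csv("results/household_afe.csv", show_col_types = FALSE)

base <- intake_per_afe(supply, afe)
readr::write_csv(base, "results/base_intakes_per_afe.csv")

med <- vapply(nutrient_columns(), function(nm) median(base[[nm]]), numeric(1))
cat(sprintf("mean household AFE: %.2f\n", mean(afe$afe)))
cat("median per-AFE daily intakes (unweighted):\n")
for (nm in nutrient_columns()) cat(sprintf("  %-16s %8.1f\n", nm, med[[nm]]))
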