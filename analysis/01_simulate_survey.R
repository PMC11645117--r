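#!/usr/bin/env Rscript
# Stage 1 - simulate the survey.
#
# Draws the default synthetic household survey: 4 analytical strata,
# 8 households per cluster (3288 households), a 60-item 7-day food module,
# and writes the raw tables (roster, consumption, design, reference
# fixtures) under results/survey/. Ground-truth per-AFE intakes and
# prevalences are stored alongside for later comparison.

library(hcesfort)

seed <- 1L
outdir <- "results/survey"

survey <- generate_survey(seed = seed)
fixtures <- generate_fixtures(seed)
write_survey_tables(survey, fixtures, outdir)
readr::write_csv(survey$ground_truth$prevalence,
                 file.path(outdir, "ground_truth_prevalence.csv"))
readr::write_csv(survey$injections, file.path(outdir, "injections.csv"))

cat(sprintf("simulated %d households (%d members, %d consumption rows)\n",
            nrow(survey$households), nrow(survey$roster),
            nrow(survey$consumption)))
cat(sprintf("injected corruption: %d outliers, %d missing quantities\n",
            sum(survey$injections$type == "outlier"),
            sum(survey$injections$type == "missing")))
cat(sprintf("tables written to %s\n", outdir))
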