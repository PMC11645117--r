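#!/usr/bin/env Rscript
# Stage 4 - model the four fortification scenarios.
#
# Applies no fortification, status quo (A*B*(1-C): legislated content times
# observed compliance less vitamin losses), full fortification (A*(1-C)),
# and full fortification without maize flour, routing fortificants through
# the vehicle equivalents (recipe-inclusive for wheat flour and oil).

library(hcesfort)

veh <- readr::read_csv("results/vehicle_equivalents.csv", show_col_types = FALSE)
base <- readr::read_csv("results/base_intakes_per_afe.csv", show_col_types = FALSE)

spec <- default_fortification_spec()
scen <- apply_scenarios(veh, base, spec)
readr::write_csv(scen, "results/scenario_intakes.csv")
readr::write_csv(spec, "results/fortification_spec.csv")

cat("fortification parameters (A mg/kg, B compliance, C loss):\n")
print(as.data.frame(spec), row.names = FALSE)
add <- scen[scen$scenario == "status_quo", ]
cat(sprintf("status quo: mean added vitamin A %.0f ug RAE/d per AFE among oil consumers\n",
            mean(add$fort_vita_rae_mcg[add$fort_vita_rae_mcg > 0])))
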