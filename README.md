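# hcesfort

Apparent micronutrient intakes and large-scale food fortification (LSFF)
scenario modelling from household consumption and expenditure survey (HCES)
food records.

Many low- and middle-income countries run HCES with a 7-day household food
module but have no national individual-level dietary survey. `hcesfort`
turns such records into population-level nutrition evidence: it converts
reported food quantities into edible-portion nutrient supplies, expresses
them per **adult female equivalent** (AFE), estimates the survey-weighted
prevalence at risk of inadequate and excess apparent intakes of five
micronutrients (iron, zinc, vitamin A, folate, vitamin B12), and models how
much mandatory fortification of cooking oil, wheat flour and maize flour
could change those risks under four compliance scenarios. Because the
microdata that motivate this pipeline are access-restricted, the package
ships a synthetic survey generator with known ground truth that emulates a
Tanzania National Panel Survey-style design (4 analytical strata, 8
households per cluster, a 60-item food list), so every stage is testable
end to end.

## The method

For household *h* with food records *f* (7-day recall), the apparent daily
intake of nutrient *n* per AFE is

```
intake(h, n) = [ Σ_f  q_f/7 · (1 − refuse_f) · density_n(f) / 100 ] / AFE(h)

AFE(h) = Σ_members EER(age, sex, weight) / EER(female 18–29.9 y)
```

with quantities converted to grams (density for volumes, portion masses for
pieces), log-scale outliers (>3 SD from the median of logs, per food item)
and missing values replaced by consumer medians, and energy requirements at
physical activity level 1.85. Children below 24 months contribute their
complementary-food energy (0/76/269/451/746 kcal/d by age band); lactating
women — women linked as mothers of a child under 24 months — add 500 kcal/d.

Fortification adds, per vehicle and nutrient, `A·B·(1−C)` mg/kg under the
**status quo** scenario and `A·(1−C)` under **full fortification**, where
*A* is the legislated content (oil: 25 mg/kg vitamin A RAE; flours:
iron 33, zinc 44, B12 0.013, folic acid 2 mg/kg), *B* the observed
compliance (oil 0.28, wheat flour 0.47, maize flour 0) and *C* the vitamin
loss fraction. Fortificants flow through vehicle *equivalents*: wheat flour
and oil embedded in bread, buns/cakes/biscuits and sweets count via recipe
mass fractions (macaroni/spaghetti deliberately does not). Folic acid
counts ×1.7 towards dietary folate equivalents for adequacy and as folic
acid mass against its upper limit.

Adequacy uses the fixed cut-point approach against harmonised average
requirements (H-AR: zinc 10.2 mg, vitamin A 490 µg RAE, folate 250 µg DFE,
B12 2 µg) — except iron, which uses the full probability approach for
menstruating women at 5% bioavailability. Excess risk uses harmonised
upper limits (iron 45 mg, zinc 25 mg EFSA / 40 mg IOM, preformed retinol
3000 µg, folic acid 1000 µg). Micronutrient gaps (25th-percentile intake
minus H-AR) and zinc safety gaps (H-UL minus 75th percentile) complete the
picture. All estimators are survey-weighted, reported nationally, by
urban/rural residence and by analytical stratum.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic survey (results land under `results/`):

```sh
Rscript analysis/01_simulate_survey.R
Rscript analysis/02_quantify_consumption.R
Rscript analysis/03_afe_standardise.R
Rscript analysis/04_fortification_scenarios.R
Rscript analysis/05_adequacy_summaries.R
```

Stage 5 prints, for the default seed:

```
national vehicle coverage (weighted):
  cooking_oil  91.3%
  wheat_flour  51.3%
  maize_flour  87.7%

national prevalence (%) at risk of inadequate intake by scenario:
       nutrient no_fortification status_quo  full full_no_maize
        iron_mg             75.6       74.6 51.47         73.44
        zinc_mg             43.2       37.0  9.40         31.71
   vita_rae_mcg             92.7       82.0 36.14         36.14
 folate_mcg_dfe             15.4       11.8  1.92          9.55
     vitb12_mcg             49.6       45.8  5.67         42.81

max |pipeline - ground truth| over 20 prevalence cells: 0.18 pp
```

Reading: about 91% of households consume cooking oil, 88% maize flour and
51% wheat flour (including flour and oil embedded in bread, cakes and
sweets). Without fortification, 92.7% of households have apparent vitamin A
intakes below the requirement of a woman aged 18–29.9 y; oil fortification
at the observed 28% compliance reduces that to 82.0%, and full compliance
across all vehicles to 36.1%. The last line compares the pipeline against
the generator's independently computed ground truth.

The same pipeline runs on real data: map the survey to the CSV schema of
`read_survey_tables()` and call
`run_pipeline(pipeline_config(simulate = FALSE, input_dir = ...))`.

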