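test_that("default parameters carry the legislated standards and compliance", {
  spec <- default_fortification_spec()
  grab <- function(v, n, col) spec[[col]][spec$vehicle == v & spec$nutrient == n]
  expect_equal(grab("cooking_oil", "vita_rae_mcg", "A"), 25)
  expect_equal(grab("wheat_flour", "iron_mg", "A"), 33)
  expect_equal(grab("wheat_flour", "zinc_mg", "A"), 44)
  expect_equal(grab("wheat_flour", "vitb12_mcg", "A"), 0.013)
  expect_equal(grab("wheat_flour", "folic_acid_mcg", "A"), 2)
  expect_equal(grab("maize_flour", "iron_mg", "A"), 33)
  expect_equal(grab("cooking_oil", "vita_rae_mcg", "B"), 0.28)
  expect_equal(grab("wheat_flour", "iron_mg", "B"), 0.47)
  expect_equal(grab("maize_flour", "iron_mg", "B"), 0)
  expect_equal(grab("wheat_flour", "iron_mg", "C"), 0) # minerals lose nothing
})

test_that("added content reproduces the scenario formulas on a parameter grid", {
  set.seed(1)
  n <- 1000
  A <- runif(n, 0, 50); B <- runif(n); C <- runif(n)
  for (i in seq_len(n)) {
    spec <- tibble::tibble(vehicle = "wheat_flour", nutrient = "iron_mg",
                           A = A[i], B = B[i], C = C[i])
    expect_identical(added_content("wheat_flour", "iron_mg", "no_fortification", spec), 0)
    expect_identical(added_content("wheat_flour", "iron_mg", "status_quo", spec),
                     A[i] * B[i] * (1 - C[i]))
    expect_identical(added_content("wheat_flour", "iron_mg", "full", spec),
                     A[i] * (1 - C[i]))
  }
})

test_that("printed worked examples hold", {
  # zero maize compliance: nothing added under status quo
  expect_equal(added_content("maize_flour", "iron_mg", "status_quo"), 0)
  expect_equal(added_content("maize_flour", "folic_acid_mcg", "status_quo"), 0)
  # oil at full fortification with zero loss carries the full 25 mg/kg
  no_loss <- default_fortification_spec()
  no_loss$C <- 0
  expect_equal(added_content("cooking_oil", "vita_rae_mcg", "full", no_loss), 25)
  # wheat flour iron under status quo: 33 * 0.47 with no mineral loss
  expect_equal(added_content("wheat_flour", "iron_mg", "status_quo"), 15.51)
  # full fortification without maize zeroes only the maize route
  expect_equal(added_content("maize_flour", "iron_mg", "full_no_maize"), 0)
  expect_equal(added_content("wheat_flour", "iron_mg", "full_no_maize"),
               added_content("wheat_flour", "iron_mg", "full"))
  expect_error(added_content("cooking_oil", "iron_mg", "full"),
               class = "hcesfort_config_error")
})

test_that("folic acid converts to dietary folate equivalents at 1.7", {
  expect_identical(folic_acid_to_dfe(2), 3.4)
  expect_identical(folic_acid_to_dfe(0), 0)
  expect_identical(folic_acid_to_dfe(1), 1.7)
  x <- runif(20, 0, 10)
  expect_equal(folic_acid_to_dfe(2 * x), 2 * folic_acid_to_dfe(x))
  expect_error(folic_acid_to_dfe(-1), class = "hcesfort_domain_error")
})

test_that("scenario application adds fortificants on the right ledgers", {
  base <- tibble::tibble(household_id = 1:2, afe = c(2, 4),
                         energy_kcal = 2000, iron_mg = 10, zinc_mg = 8,
                         vita_rae_mcg = 200, retinol_mcg = 20,
                         folate_mcg_dfe = 300, folic_acid_mcg = 0, vitb12_mcg = 1)
  veh <- tibble::tibble(household_id = 1:2, cooking_oil = c(20, 0),
                        wheat_flour = c(100, 0), maize_flour = c(0, 0))
  spec <- default_fortification_spec()
  spec$C <- 0

  none <- apply_scenario(veh, base, "no_fortification", spec)
  expect_equal(none[, nutrient_columns()], base[, nutrient_columns()])

  full <- apply_scenario(veh, base, "full", spec)
  # household 1: oil 20 g/d -> 0.5 mg RAE/d; wheat 100 g/d: Fe 3.3 mg, Zn 4.4,
  # B12 1.3 ug, folic acid 200 ug (340 ug DFE); all divided by afe = 2
  expect_equal(full$vita_rae_mcg[1], 200 + 500 / 2)
  expect_equal(full$retinol_mcg[1], 20 + 500 / 2)
  expect_equal(full$iron_mg[1], 10 + 3.3 / 2)
  expect_equal(full$zinc_mg[1], 8 + 4.4 / 2)
  expect_equal(full$vitb12_mcg[1], 1 + 1.3 / 2)
  expect_equal(full$folic_acid_mcg[1], 0 + 200 / 2)
  expect_equal(full$folate_mcg_dfe[1], 300 + 340 / 2)
  expect_equal(full$energy_kcal[1], 2000) # fortificants add no energy

  # a household consuming no vehicles is invariant across scenarios
  for (sc in scenario_names()) {
    out <- apply_scenario(veh, base, sc, spec)
    expect_equal(out[2, nutrient_columns()], base[2, nutrient_columns()])
  }
})

test_that("status quo contribution is linear in compliance", {
  base <- tibble::tibble(household_id = 1, afe = 1, energy_kcal = 0, iron_mg = 0,
                         zinc_mg = 0, vita_rae_mcg = 0, retinol_mcg = 0,
                         folate_mcg_dfe = 0, folic_acid_mcg = 0, vitb12_mcg = 0)
  veh <- tibble::tibble(household_id = 1, cooking_oil = 10, wheat_flour = 50,
                        maize_flour = 100)
  s1 <- default_fortification_spec(compliance = c(cooking_oil = 0.14,
                                                  wheat_flour = 0.2,
                                                  maize_flour = 0.1))
  s2 <- default_fortification_spec(compliance = c(cooking_oil = 0.28,
                                                  wheat_flour = 0.4,
                                                  maize_flour = 0.2))
  r1 <- apply_scenario(veh, base, "status_quo", s1)
  r2 <- apply_scenario(veh, base, "status_quo", s2)
  for (nm in setdiff(nutrient_columns(), "energy_kcal")) {
    expect_equal(r2[[nm]], 2 * r1[[nm]])
  }
})

test_that("scenario ordering holds for every household and nutrient", {
  s <- generate_survey(small_design(), seed = 21)
  res <- run_pipeline(pipeline_config(design = small_design(), seed = 21))
  wide <- tidyr::pivot_wider(
    res$scenario_intakes[, c("household_id", "scenario", nutrient_columns())],
    names_from = "scenario",
    values_from = dplyr::all_of(nutrient_columns()))
  for (nm in nutrient_columns()) {
    nf <- wide[[paste0(nm, "_no_fortification")]]
    sq <- wide[[paste0(nm, "_status_quo")]]
    fu <- wide[[paste0(nm, "_full")]]
    fnm <- wide[[paste0(nm, "_full_no_maize")]]
    expect_true(all(nf <= sq + 1e-12))
    expect_true(all(sq <= fu + 1e-12))
    expect_true(all(fnm <= fu + 1e-12))
  }
})
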