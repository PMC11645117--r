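test_that("identical seeds reproduce the survey byte for byte", {
  a <- generate_survey(small_design(), seed = 3)
  b <- generate_survey(small_design(), seed = 3)
  expect_identical(a$households, b$households)
  expect_identical(a$roster, b$roster)
  expect_identical(a$consumption, b$consumption)
  expect_identical(a$injections, b$injections)
  expect_equal(a$ground_truth$prevalence, b$ground_truth$prevalence)

  c <- generate_survey(small_design(), seed = 4)
  expect_false(identical(a$consumption, c$consumption))
})

test_that("coverage one yields a consumption row per household, coverage zero none", {
  model <- single_stratum_model()
  model$items$coverage[model$items$food_code == 1001] <- 1
  model$items$coverage[model$items$food_code == 101] <- 0
  s <- generate_survey(single_stratum_design(clusters = 1, hpc = 8), model, fx, seed = 1)
  expect_equal(nrow(s$households), 8)
  expect_equal(sum(s$consumption$food_code == 1001), 8)
  expect_equal(sum(s$consumption$food_code == 101), 0)
})

test_that("empirical coverage recovers the configured probability", {
  # single stratum, n = 5000, tolerance 3 binomial standard errors
  model <- single_stratum_model()
  model$items$coverage[model$items$food_code == 1001] <- 0.91
  s <- generate_survey(single_stratum_design(clusters = 625), model, fx, seed = 2)
  n <- nrow(s$households)
  expect_equal(n, 5000)
  p_hat <- sum(s$consumption$food_code == 1001) / n
  expect_lt(abs(p_hat - 0.91), 3 * sqrt(0.91 * 0.09 / n))
})

test_that("national oil coverage emulates the observed 91% across four strata", {
  model <- default_consumption_model()
  model$items$coverage[model$items$food_code == 1001] <- 0.91
  s <- generate_survey(model = model, fixtures = fx, seed = 1)
  hh <- s$households
  consumed <- hh$household_id %in%
    s$consumption$household_id[s$consumption$food_code == 1001]
  cov_w <- 100 * sum(hh$weight[consumed]) / sum(hh$weight)
  expect_lt(abs(cov_w - 91), 2)
})

test_that("generated quantities recover the configured lognormal median", {
  s <- generate_survey(single_stratum_design(clusters = 625),
                       single_stratum_model(), fx, seed = 5)
  oil <- s$consumption[s$consumption$food_code == 1001 & !is.na(s$consumption$quantity), ]
  afe <- s$ground_truth$afe
  gpd_afe <- oil$quantity * 1000 * 0.92 / 7 /
    afe$afe[match(oil$household_id, afe$household_id)]
  expect_lt(abs(median(gpd_afe) / 36 - 1), 0.05) # configured Dar es Salaam median
})

test_that("stored ground truth equals a straight-line recomputation of one household", {
  s <- generate_survey(small_design(), seed = 8)
  gt <- s$ground_truth
  hid <- gt$base_intakes$household_id[5]
  rows <- s$consumption[s$consumption$household_id == hid, ]
  inj <- s$injections[s$injections$household_id == hid, ]
  # undo any injected corruption to recover true quantities
  for (i in seq_len(nrow(inj))) {
    rows$quantity[rows$food_code == inj$food_code[i]] <- inj$true_quantity[i]
  }
  iron <- 0
  for (i in seq_len(nrow(rows))) {
    code <- rows$food_code[i]
    g7 <- switch(rows$unit[i],
      kg = rows$quantity[i] * 1000,
      g = rows$quantity[i],
      L = rows$quantity[i] * 1000 *
        fx$refuse_density$density_g_ml[fx$refuse_density$food_code == code],
      pieces = rows$quantity[i] * fx$portions$portion_g[fx$portions$food_code == code])
    refuse <- fx$refuse_density$refuse_fraction[fx$refuse_density$food_code == code]
    iron <- iron + g7 / 7 * (1 - refuse) / 100 * fx$fct$iron_mg[fx$fct$food_code == code]
  }
  afe <- gt$afe$afe[gt$afe$household_id == hid]
  expect_equal(gt$base_intakes$iron_mg[gt$base_intakes$household_id == hid],
               iron / afe)
})

test_that("fixtures are complete and internally consistent", {
  fl <- fx$food_list
  expect_equal(nrow(fl), 60)
  expect_setequal(fl$food_code, fx$fct$food_code)
  pieces <- fl$food_code[fl$report_unit == "pieces"]
  expect_true(all(pieces %in% fx$portions$food_code))
  liquids <- fl$food_code[fl$report_unit %in% c("L", "mL")]
  dens <- fx$refuse_density$density_g_ml[match(liquids, fx$refuse_density$food_code)]
  expect_true(all(dens > 0))
  expect_true(all(fx$refuse_density$refuse_fraction >= 0 &
                    fx$refuse_density$refuse_fraction < 1))
  # frequency weights of concatenated items are normalised
  wsum <- tapply(fx$hbs_weights$hbs_weight, fx$hbs_weights$composite_code, sum)
  expect_equal(as.numeric(wsum), rep(1, length(wsum)))
  # recipe fractions are valid mass fractions, at most 1 in total per product
  expect_true(all(fx$recipes$mass_fraction > 0 & fx$recipes$mass_fraction <= 1))
  fsum <- tapply(fx$recipes$mass_fraction, fx$recipes$product_code, sum)
  expect_true(all(fsum <= 1))
  # composite rows are the weighted mean of their components
  comp <- fx$components[fx$components$composite_code == 501, ]
  expect_equal(fx$fct$iron_mg[fx$fct$food_code == 501],
               sum(comp$hbs_weight * comp$iron_mg) / sum(comp$hbs_weight))
})

test_that("invalid configurations raise configuration errors", {
  expect_error(survey_design(clusters_per_stratum = c(A = -1)),
               class = "hcesfort_config_error")
  expect_error(survey_design(clusters_per_stratum = c(A = 2),
                             pop_share = c(A = 0.5)),
               class = "hcesfort_config_error")
  model <- single_stratum_model()
  model$items$coverage[1] <- 1.2
  expect_error(generate_survey(single_stratum_design(1), model, fx, seed = 1),
               class = "hcesfort_config_error")
  expect_error(generate_survey(single_stratum_design(1),
                               single_stratum_model(missing_rate = 2), fx, seed = 1),
               class = "hcesfort_config_error")
})
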