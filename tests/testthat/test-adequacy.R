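test_that("weighted quantile generalises the interpolated sample quantile", {
  expect_equal(weighted_quantile(1:9, q = 0.5), 5)
  expect_equal(weighted_quantile(c(4, 1, 7), q = 0), 1)
  expect_equal(weighted_quantile(c(4, 1, 7), q = 1), 7)
  # the printed two-point case: weight mass pulls the median onto the 2 side
  expect_equal(weighted_quantile(c(1, 2), c(1, 3), 0.5), 2)

  # equal weights reduce to the plain type-7 quantile
  set.seed(7)
  x <- rnorm(37)
  qs <- c(0, 0.1, 0.25, 0.5, 0.66, 0.75, 0.9, 1)
  expect_equal(weighted_quantile(x, q = qs),
               unname(quantile(x, qs, type = 7)))

  expect_error(weighted_quantile(numeric(0), q = 0.5))
  expect_error(weighted_quantile(1:3, q = 1.5))
  expect_error(weighted_quantile(1:3, c(1, -1, 1), 0.5))
})

test_that("weighted estimators equal brute-force weight replication", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- round(rlnorm(n, 2, 1), 3)
    w <- sample(1:6, n, replace = TRUE)
    rep_x <- rep(x, w)
    qs <- runif(3)
    expect_equal(weighted_quantile(x, w, qs),
                 unname(quantile(rep_x, qs, type = 7)))
    thr <- sample(x, 1) * runif(1, 0.5, 1.5)
    expect_equal(prevalence_inadequate_cutpoint(x, w, thr),
                 100 * mean(rep_x < thr))
    expect_equal(
      prevalence_excess(x, w, "iron_mg",
                        thresholds = list(hul = c(iron_mg = thr))),
      100 * mean(rep_x > thr))
  }
})

test_that("cut-point prevalence counts weighted households below the requirement", {
  expect_equal(prevalence_inadequate_cutpoint(c(5, 15), har = 10.2), 50)
  expect_equal(prevalence_inadequate_cutpoint(c(11, 15, 20), har = 10.2), 0)
  expect_equal(prevalence_inadequate_cutpoint(c(5, 15), c(3, 1), 10.2), 75)
})

test_that("full probability iron estimator matches its oracles", {
  # a step risk curve reduces exactly to the cut-point estimator
  set.seed(3)
  for (i in 1:20) {
    x <- rlnorm(50, 3, 0.5)
    w <- runif(50, 0.5, 2)
    t <- exp(rnorm(1, 3, 0.5))
    expect_equal(prevalence_inadequate_iron(x, w, step_risk_curve(t)),
                 prevalence_inadequate_cutpoint(x, w, t))
  }

  # flat risk region: prevalence equals 100 r
  flat <- tibble::tibble(intake_mg = c(0, 100), risk = c(0.4, 0.4))
  expect_equal(prevalence_inadequate_iron(c(10, 20, 30), curve = flat), 40)

  # piecewise linear fixture, hand-summed expectation
  curve <- tibble::tibble(intake_mg = c(0, 10, 20, 30), risk = c(1, 0.8, 0.3, 0.1))
  intakes <- c(5, 10, 15, 25, 35)
  w <- c(1, 2, 1, 1, 1)
  hand <- (1 * 0.9 + 2 * 0.8 + 1 * 0.55 + 1 * 0.2 + 1 * 0.1) / 6
  expect_equal(prevalence_inadequate_iron(intakes, w, curve), 100 * hand)

  # default curve is a valid monotone risk function anchored at 1
  dc <- default_iron_risk_curve()
  expect_equal(dc$risk[1], 1)
  expect_true(all(diff(dc$risk) <= 0))
  expect_true(all(dc$risk >= 0 & dc$risk <= 1))
})

test_that("excess prevalence respects the upper limits and allowed nutrients", {
  expect_equal(prevalence_excess(c(20, 30), nutrient = "zinc_mg",
                                 zn_authority = "efsa"), 50)
  expect_equal(prevalence_excess(c(20, 30), nutrient = "zinc_mg",
                                 zn_authority = "iom"), 0)
  expect_equal(prevalence_excess(c(500, 2900), nutrient = "retinol_mcg"), 0)
  expect_error(prevalence_excess(c(100, 200), nutrient = "folate_mcg_dfe"),
               class = "hcesfort_unsupported_nutrient")
  expect_error(prevalence_excess(c(1, 2), nutrient = "vitb12_mcg"),
               class = "hcesfort_unsupported_nutrient")
})

test_that("micronutrient and safety gaps are signed quantile differences", {
  x <- rep(300, 8)
  expect_equal(micronutrient_gap(x, har = 250), 50)
  expect_equal(micronutrient_gap(x, har = 300), 0)
  expect_equal(safety_gap(rep(32.4, 5), hul = 25), -7.4)
  expect_equal(safety_gap(rep(32.4, 5), hul = 40), 7.6)
  expect_equal(safety_gap(rep(10, 3), hul = 10), 0)

  # the two zinc authorities always differ by exactly 15 mg
  set.seed(5)
  y <- rlnorm(200, 3, 0.6)
  w <- runif(200, 0.5, 2)
  expect_equal(safety_gap(y, w, 40) - safety_gap(y, w, 25), 15)
})

test_that("stratified summaries degenerate correctly on one stratum", {
  res <- run_pipeline(pipeline_config(design = single_stratum_design(10),
                                      model = single_stratum_model(),
                                      seed = 31))
  sm <- res$summaries
  for (tab in c("coverage", "inadequacy", "excess", "gaps")) {
    nat <- sm[[tab]][sm[[tab]]$domain == "national", ]
    str <- sm[[tab]][sm[[tab]]$domain == "Dar es Salaam", ]
    val <- intersect(c("coverage_pct", "prevalence_pct", "gap"), names(nat))
    expect_equal(nat[[val]], str[[val]])
  }
  # quantile ordering of consumption among consumers
  cons <- sm$consumption[sm$consumption$n_consumers > 0, ]
  expect_true(all(cons$p25 <= cons$median & cons$median <= cons$p75))
  expect_true(all(sm$inadequacy$prevalence_pct >= 0 &
                    sm$inadequacy$prevalence_pct <= 100))
})

test_that("coverage is 100% when every household consumes the vehicle", {
  model <- single_stratum_model()
  model$items$coverage[model$items$food_code == 1001] <- 1
  res <- run_pipeline(pipeline_config(design = single_stratum_design(4),
                                      model = model, seed = 32))
  cov <- res$summaries$coverage
  expect_equal(cov$coverage_pct[cov$domain == "national" &
                                  cov$vehicle == "cooking_oil"], 100)
})
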