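#' Survey design configuration
#'
#' Stratified two-stage design in the style of a national panel survey: four
#' analytical strata, clusters drawn within strata, eight households per
#' cluster. Survey weights are the inverse stratum sampling fraction
#' (population share over sample share) times multiplicative uniform noise,
#' which exercises weighted estimators without replicating any particular
#' weight construction. Default cluster counts give 3288 households,
#' matching the analysed sample size of a national refresh panel
#' (539/529/1757/465 by stratum) to within rounding by full clusters.
#'
#' @param clusters_per_stratum Named integer vector of cluster counts.
#' @param households_per_cluster Households drawn per cluster (default 8).
#' @param pop_share Named population shares per stratum (sum to 1).
#' @param urban_share Probability a household of the stratum is urban.
#' @param weight_noise Range of the multiplicative weight noise.
#' @return A `hcesfort_design` list.
#' @export
survey_design <- function(clusters_per_stratum = c("Dar es Salaam" = 67,
                                                   "Mainland other urban" = 66,
                                                   "Mainland rural" = 220,
                                                   "Zanzibar" = 58),
                          households_per_cluster = 8,
                          pop_share = c("Dar es Salaam" = 0.10,
                                        "Mainland other urban" = 0.19,
                                        "Mainland rural" = 0.68,
                                        "Zanzibar" = 0.03),
                          urban_share = c("Dar es Salaam" = 1,
                                          "Mainland other urban" = 1,
                                          "Mainland rural" = 0,
                                          "Zanzibar" = 0.57),
                          weight_noise = c(0.8, 1.2)) {
  strata <- names(clusters_per_stratum)
  if (is.null(strata) || any(!nzchar(strata))) abort("strata must be named",
                                                    class = "hcesfort_config_error")
  if (any(clusters_per_stratum < 1) || households_per_cluster < 1) {
    abort("cluster and household counts must be positive",
          class = "hcesfort_config_error")
  }
  if (any(pop_share[strata] < 0) || abs(sum(pop_share[strata]) - 1) > 1e-8) {
    abort("population shares must be non-negative and sum to 1",
          class = "hcesfort_config_error")
  }
  if (any(urban_share[strata] < 0 | urban_share[strata] > 1)) {
    abort("urban shares must lie in [0,1]", class = "hcesfort_config_error")
  }
  structure(list(strata = strata,
                 clusters_per_stratum = clusters_per_stratum,
                 households_per_cluster = households_per_cluster,
                 pop_share = pop_share[strata],
                 urban_share = urban_share[strata],
                 weight_noise = weight_noise),
            class = "hcesfort_design")
}

# item-level consumption parameters per stratum, in the column order
# cov/med = Dar es Salaam, Mainland other urban, Mainland rural, Zanzibar.
# Medians are g/day per AFE among consumers; vehicle and vehicle-product
# rows are set to the published stratified coverage and consumption pattern
# (oil and maize flour near-universal, wheat flour urban-skewed, maize
# heaviest in rural mainland and light in Zanzibar); remaining items are
# plausible for the setting, with every coverage floored at 0.10 so each
# stratum-item consumer group is large enough for a stable outlier spread.
consumption_parameters <- function() {
  tibble::tribble(
    ~food_code, ~cov1, ~cov2, ~cov3, ~cov4, ~med1, ~med2, ~med3, ~med4, ~sdlog, ~p_purchase, ~p_own,
    101L, .85, .80, .60, .90, 120, 110,  90, 150, .50, .85, .10,
    102L, .10, .10, .15, .10,  60,  60,  80,  60, .50, .40, .55,
    103L, .10, .15, .25, .10,  50,  60,  80,  40, .60, .45, .50,
    104L, .10, .10, .30, .10,  80, 100, 150,  60, .50, .40, .55,
    105L, .87, .88, .90, .54, 170, 190, 302,  57, .50, .62, .30,
    106L, .10, .10, .12, .10,  40,  50,  70,  30, .50, .40, .55,
    107L, .10, .10, .15, .10,  50,  60,  90,  40, .50, .55, .40,
    108L, .30, .18, .12, .45,  60,  55,  40,  90, .55, .98, .01,
    109L, .75, .45, .15, .50,  80,  70,  50,  80, .55, .99, .00,
    110L, .45, .28, .10, .30,  40,  35,  25,  35, .60, .99, .00,
    111L, .20, .12, .10, .15,  40,  35,  30,  35, .60, 1.0, .00,
    112L, .10, .10, .10, .10,  30,  30,  30,  30, .60, .80, .15,
    201L, .10, .15, .30, .20,  80,  90, 120,  80, .60, .35, .60,
    202L, .10, .10, .25, .10,  60,  70, 100,  60, .55, .45, .50,
    203L, .15, .20, .30, .15,  90, 100, 130,  80, .60, .40, .55,
    204L, .35, .30, .15, .20,  80,  80,  70,  60, .60, .80, .15,
    205L, .20, .20, .15, .10,  90,  90, 100,  70, .60, .55, .40,
    206L, .10, .10, .10, .10,  60,  60,  70,  50, .60, .50, .45,
    301L, .90, .85, .70, .90,  40,  38,  30,  45, .55, .97, .01,
    302L, .20, .15, .10, .15,  10,  10,   8,  10, .60, 1.0, .00,
    303L, .10, .10, .10, .10,   8,   8,   8,   8, .60, .70, .25,
    401L, .65, .70, .75, .55,  55,  60,  70,  45, .55, .55, .40,
    402L, .20, .25, .30, .25,  40,  40,  50,  35, .55, .55, .40,
    403L, .15, .20, .30, .10,  20,  20,  30,  15, .60, .55, .40,
    404L, .30, .25, .20, .70,  40,  40,  40,  60, .60, .70, .25,
    405L, .10, .10, .10, .10,  10,  10,  10,  10, .60, .80, .15,
    501L, .95, .92, .85, .90,  90,  85,  70,  80, .55, .75, .20,
    502L, .70, .72, .80, .60,  80,  85, 100,  60, .90, .45, .50,
    503L, .10, .10, .12, .10,  10,  10,  12,   8, .60, .80, .15,
    601L, .35, .30, .25, .30,  60,  60,  60,  50, .60, .60, .35,
    602L, .25, .22, .18, .30,  50,  50,  40,  60, .60, .55, .40,
    603L, .30, .28, .25, .35,  80,  80,  80,  90, .60, .50, .45,
    604L, .10, .10, .12, .10,  60,  60,  80,  50, .60, .50, .45,
    605L, .10, .10, .10, .10,   8,   8,   8,   8, .60, .90, .05,
    701L, .55, .45, .25, .35,  40,  35,  30,  30, .60, .95, .03,
    702L, .12, .12, .10, .10,  30,  30,  30,  25, .60, .85, .12,
    703L, .10, .10, .10, .10,  30,  30,  30,  30, .60, .90, .08,
    704L, .25, .22, .15, .25,  45,  40,  40,  45, .60, .70, .28,
    705L, .10, .10, .10, .10,  10,  10,  15,  10, .60, .30, .65,
    706L, .10, .10, .10, .10,  20,  20,  20,  20, .60, .90, .05,
    707L, .40, .30, .15, .30,  25,  22,  18,  22, .60, .75, .22,
    801L, .55, .40, .30, .75,  55,  45,  40,  70, .60, .85, .12,
    802L, .30, .40, .45, .35,  15,  18,  20,  15, .60, .90, .05,
    803L, .10, .10, .10, .10,  10,  10,  10,  10, .60, 1.0, .00,
    804L, .10, .10, .10, .10,  10,  10,  10,  10, .60, 1.0, .00,
    901L, .30, .35, .30, .25,  80,  90, 100,  60, .60, .60, .35,
    902L, .10, .10, .10, .10,  10,  10,   8,  10, .60, 1.0, .00,
    903L, .10, .10, .10, .10,  30,  30,  30,  30, .60, .95, .03,
    1001L, .98, .93, .83, .82, 36,  30,  17,  25, .60, 1.0, .00,
    1002L, .10, .10, .10, .10,   8,   8,   8,   8, .60, .95, .03,
    1003L, .10, .10, .10, .10,   8,   8,   8,   8, .60, .90, .08,
    1101L, .50, .45, .35, .55,   3,   3,   2,   3, .60, 1.0, .00,
    1102L, .10, .10, .10, .10,   3,   3,   3,   3, .60, 1.0, .00,
    1103L, .35, .25, .10, .25,  60,  50,  40,  50, .60, 1.0, .00,
    1104L, .15, .10, .10, .10, 150, 120, 100, 120, .60, 1.0, .00,
    1105L, .10, .10, .15, .10, 150, 150, 200, 100, .70, .60, .35,
    1106L, .10, .10, .10, .10, 120, 120, 100, 100, .60, 1.0, .00,
    1107L, .10, .10, .10, .10,  30,  30,  30,  30, .60, 1.0, .00,
    1201L, .95, .95, .95, .95,   5,   5,   5,   5, .50, 1.0, .00,
    1202L, .40, .40, .30, .50,   4,   4,   4,   4, .60, .90, .05
  )
}

#' Default consumption model
#'
#' Per (stratum, food item): the probability that a household consumes the
#' item during the 7-day recall (coverage), the median consumption among
#' consumers in g/day per AFE, the log-scale spread, and the distribution of
#' the acquisition source. Quantities are drawn lognormally (logs truncated
#' at +/- `trunc_sd` standard deviations, keeping the distribution
#' right-skewed while bounding the natural spread so that the >3 SD
#' log-outlier rule flags exactly the injected corruptions), scaled by the
#' household's AFE so that per-AFE distributions are size-invariant.
#' Corruption is injected on top: a fraction `outlier_rate` of rows in
#' sufficiently large stratum-item groups (at most `max_injections_per_group`
#' each) is multiplied by `exp(outlier_k * sdlog)`, and a fraction
#' `missing_rate` of quantities is blanked.
#'
#' @param strata Stratum labels the model covers.
#' @param missing_rate Fraction of quantities blanked (default 0.002).
#' @param outlier_rate Fraction of rows inflated into detectable outliers.
#' @param outlier_k Outlier inflation in units of the item's sdlog.
#' @param trunc_sd Truncation of the base log-quantity distribution.
#' @param min_group_injection Minimum consumers in a stratum-item group for
#'   corruption injection.
#' @param max_injections_per_group Outlier injection cap per group.
#' @return A `hcesfort_model` list with an `items` tibble and the scalar
#'   corruption settings.
#' @export
default_consumption_model <- function(strata = c("Dar es Salaam",
                                                 "Mainland other urban",
                                                 "Mainland rural",
                                                 "Zanzibar"),
                                      missing_rate = 0.002,
                                      outlier_rate = 0.005,
                                      outlier_k = 9,
                                      trunc_sd = 1.5,
                                      min_group_injection = 30,
                                      max_injections_per_group = 2) {
  par <- consumption_parameters()
  items <- purrr::map_dfr(seq_along(strata), function(i) {
    tibble::tibble(
      stratum = strata[i],
      food_code = par$food_code,
      coverage = par[[paste0("cov", i)]],
      median_gpd_afe = par[[paste0("med", i)]],
      sdlog = par$sdlog,
      p_purchase = par$p_purchase,
      p_own = par$p_own,
      p_gift = pmax(0, 1 - par$p_purchase - par$p_own)
    )
  })
  structure(list(items = items,
                 missing_rate = missing_rate,
                 outlier_rate = outlier_rate,
                 outlier_k = outlier_k,
                 trunc_sd = trunc_sd,
                 min_group_injection = min_group_injection,
                 max_injections_per_group = max_injections_per_group),
            class = "hcesfort_model")
}
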