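#' Harmonised requirement and upper-limit thresholds
#'
#' Harmonised average requirements (H-AR) for a non-pregnant, non-lactating
#' woman aged 18-29.9 years: zinc 10.2 mg (unrefined diet), vitamin A 490 ug
#' RAE, folate 250 ug DFE, vitamin B12 2 ug. Iron adequacy is not assessed by
#' cut-point but with the full probability approach (see
#' [default_iron_risk_curve()]). Harmonised upper limits (H-UL): iron 45 mg,
#' zinc 25 mg (EFSA) / 40 mg (IOM), preformed retinol 3000 ug, folic acid
#' 1000 ug. Excess risk is not assessed for folate or B12 (low toxicity
#' potential).
#'
#' @return List with `har` and `hul` named numeric vectors.
#' @export
default_thresholds <- function() {
  list(
    har = c(zinc_mg = 10.2, vita_rae_mcg = 490, folate_mcg_dfe = 250, vitb12_mcg = 2),
    hul = c(iron_mg = 45, zinc_mg_efsa = 25, zinc_mg_iom = 40,
            retinol_mcg = 3000, folic_acid_mcg = 1000)
  )
}

#' Default iron inadequacy risk curve (full probability approach)
#'
#' Probability that a menstruating woman's iron requirement exceeds a given
#' daily intake, at 5% bioavailability. The default models the absorbed-iron
#' requirement of menstruating women as lognormal with median 1.46 mg/d and
#' a 95th percentile at twice the median (right-skewed, reflecting
#' menstrual-loss variation), translated to dietary intake by dividing by
#' the bioavailability. Shipped as an interpolation table so any published
#' requirement distribution can be substituted.
#'
#' @param bioavailability Fraction of dietary iron absorbed (default 0.05).
#' @param median_absorbed_mg Median absorbed requirement, mg/d.
#' @param p95_over_median Ratio of the 95th percentile to the median.
#' @param grid_max_mg Upper end of the intake grid (risk ~ 0 well before).
#' @return Tibble with `intake_mg` and `risk` columns; risk is non-increasing
#'   from 1 at zero intake. Evaluated by linear interpolation.
#' @export
default_iron_risk_curve <- function(bioavailability = 0.05,
                                    median_absorbed_mg = 1.46,
                                    p95_over_median = 2,
                                    grid_max_mg = 150) {
  sdlog <- log(p95_over_median) / qnorm(0.95)
  meanlog <- log(median_absorbed_mg / bioavailability)
  grid <- seq(0, grid_max_mg, by = 0.5)
  risk <- c(1, 1 - pnorm((log(grid[-1]) - meanlog) / sdlog))
  tibble::tibble(intake_mg = grid, risk = risk)
}

#' Degenerate step risk curve
#'
#' A risk curve equal to 1 below `threshold` and 0 at or above it; with this
#' curve the full probability estimator reduces exactly to the fixed
#' cut-point estimator.
#'
#' @param threshold Intake threshold.
#' @return A two-row risk curve evaluated with step (left-constant)
#'   interpolation.
#' @export
step_risk_curve <- function(threshold) {
  curve <- tibble::tibble(intake_mg = c(0, threshold), risk = c(1, 0))
  attr(curve, "interpolation") <- "step"
  curve
}

eval_risk_curve <- function(curve, intakes) {
  stopifnot(all(diff(curve$risk) <= 0), all(curve$risk >= 0 & curve$risk <= 1))
  method <- attr(curve, "interpolation")
  if (is.null(method)) method <- "linear"
  approx(curve$intake_mg, curve$risk, xout = pmax(intakes, 0),
         method = if (method == "step") "constant" else "linear",
         f = 0, rule = 2)$y
}

#' Weighted interpolated quantile
#'
#' Generalises the standard interpolated sample quantile (type 7) to
#' weighted data: with the observations sorted, the quantile is read at
#' position `h = 1 + (W - 1) q` along the cumulative-weight axis (`W` the
#' summed weight), interpolating linearly between the values spanning `h`.
#' With unit weights this is exactly the plain type-7 quantile, and with
#' integer weights it equals the type-7 quantile of the weight-replicated
#' sample; the summed weight therefore plays the role of the effective
#' sample size. Survey weights on their natural scale satisfy this.
#'
#' @param x Numeric values.
#' @param w Positive weights (default unit weights).
#' @param q Quantile levels in `[0, 1]` (vectorised).
#' @return Numeric vector of quantiles, one per element of `q`.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), q) {
  if (length(x) == 0) abort("empty input")
  if (length(w) != length(x)) abort("weights must match values in length")
  if (any(is.na(x)) || any(is.na(w)) || any(w <= 0)) {
    abort("values must be non-missing and weights positive")
  }
  if (any(q < 0 | q > 1)) abort("quantile levels must lie in [0, 1]")
  ord <- order(x)
  xs <- x[ord]
  cw <- cumsum(w[ord])
  W <- cw[length(cw)]
  value_at <- function(u) {
    u <- pmin(pmax(u, cw[1] * 0), W)
    k <- findInterval(u, cw, left.open = TRUE) + 1
    k <- pmin(k, length(xs))
    xs[k]
  }
  h <- 1 + (W - 1) * q
  h <- pmin(pmax(h, 1), W)
  lo <- floor(h)
  f <- h - lo
  value_at(lo) * (1 - f) + value_at(pmin(lo + 1, W)) * f
}

#' Prevalence at risk of inadequate intake (fixed cut-point)
#'
#' Survey-weighted share of households whose per-AFE intake falls below the
#' harmonised average requirement.
#'
#' @param intakes Per-AFE daily intakes.
#' @param weights Survey weights (default unweighted).
#' @param har Harmonised average requirement (same unit as `intakes`).
#' @return Prevalence in percent.
#' @export
prevalence_inadequate_cutpoint <- function(intakes, weights = rep(1, length(intakes)), har) {
  if (length(intakes) == 0) abort("empty input")
  stopifnot(har > 0, all(weights > 0))
  100 * sum(weights[intakes < har]) / sum(weights)
}

#' Prevalence at risk of inadequate iron intake (full probability approach)
#'
#' The weighted mean, over households, of the probability that the iron
#' requirement of a menstruating woman (at the stated bioavailability)
#' exceeds the household's per-AFE iron intake. No confidence interval is
#' produced for this estimator.
#'
#' @param intakes Per-AFE daily iron intakes, mg/d.
#' @param weights Survey weights.
#' @param curve Risk curve (see [default_iron_risk_curve()]).
#' @return Prevalence in percent.
#' @export
prevalence_inadequate_iron <- function(intakes, weights = rep(1, length(intakes)),
                                       curve = default_iron_risk_curve()) {
  if (length(intakes) == 0) abort("empty input")
  risk <- eval_risk_curve(curve, intakes)
  100 * sum(weights * risk) / sum(weights)
}

#' Prevalence of excess intake above the harmonised upper limit
#'
#' Assessed for iron, zinc (under the EFSA and/or IOM upper limit),
#' preformed retinol and folic acid only; folate and vitamin B12 have low
#' toxicity potential and requesting them is an error.
#'
#' @param intakes Per-AFE daily intakes of the nutrient.
#' @param weights Survey weights.
#' @param nutrient One of `iron_mg`, `zinc_mg`, `retinol_mcg`,
#'   `folic_acid_mcg`.
#' @param thresholds Threshold set from [default_thresholds()].
#' @param zn_authority For zinc: `efsa` (25 mg) or `iom` (40 mg).
#' @return Prevalence in percent (weighted share with intake above the
#'   upper limit).
#' @export
prevalence_excess <- function(intakes, weights = rep(1, length(intakes)),
                              nutrient, thresholds = default_thresholds(),
                              zn_authority = c("efsa", "iom")) {
  allowed <- c("iron_mg", "zinc_mg", "retinol_mcg", "folic_acid_mcg")
  if (!nutrient %in% allowed) {
    abort(sprintf("excess risk is not assessed for '%s' (only %s)", nutrient,
                  paste(allowed, collapse = ", ")),
          class = "hcesfort_unsupported_nutrient")
  }
  hul <- if (nutrient == "zinc_mg") {
    thresholds$hul[paste0("zinc_mg_", match.arg(zn_authority))]
  } else {
    thresholds$hul[nutrient]
  }
  100 * sum(weights[intakes > hul]) / sum(weights)
}

#' Micronutrient gap at the 25th percentile
#'
#' Weighted 25th-percentile apparent intake minus the harmonised average
#' requirement; a negative gap approximates the additional dietary supply
#' needed from fortification.
#'
#' @inheritParams prevalence_inadequate_cutpoint
#' @return Signed gap in the nutrient's unit.
#' @export
micronutrient_gap <- function(intakes, weights = rep(1, length(intakes)), har) {
  stopifnot(har > 0)
  weighted_quantile(intakes, weights, 0.25) - har
}

#' Safety gap at the 75th percentile
#'
#' Harmonised upper limit minus the weighted 75th-percentile apparent
#' intake; positive values indicate safe intakes.
#'
#' @inheritParams prevalence_inadequate_cutpoint
#' @param hul Harmonised upper intake level.
#' @return Signed gap in the nutrient's unit.
#' @export
safety_gap <- function(intakes, weights = rep(1, length(intakes)), hul) {
  stopifnot(hul > 0)
  hul - weighted_quantile(intakes, weights, 0.75)
}

# analysis domains: national, urban/rural, and each analytical stratum
domain_list <- function(households) {
  doms <- list(national = rep(TRUE, nrow(households)),
               urban = households$urban,
               rural = !households$urban)
  for (s in unique(households$stratum)) doms[[s]] <- households$stratum == s
  doms
}

#' Survey-weighted summaries by scenario, nutrient and stratum
#'
#' Produces the pipeline's reporting tables: fortifiable-vehicle coverage
#' and per-AFE consumption among consumers (median and quartiles), the
#' prevalence at risk of inadequate intakes (fixed cut-point for zinc,
#' vitamin A, folate and B12; full probability for iron), the prevalence of
#' excess intakes (iron, zinc under both upper-limit authorities, preformed
#' retinol, folic acid), and the micronutrient and safety gaps - each for
#' the national domain, urban/rural residence and every analytical stratum.
#'
#' @param results Scenario intake table from [apply_scenarios()].
#' @param veh Vehicle equivalents from [vehicle_equivalents()].
#' @param households Household design table (`household_id`, `stratum`,
#'   `urban`, `weight`).
#' @param thresholds Threshold set from [default_thresholds()].
#' @param iron_curve Iron risk curve.
#' @param weighted Use survey weights (default) or unit weights.
#' @return List of tidy tibbles: `coverage`, `consumption`, `inadequacy`,
#'   `excess`, `gaps`.
#' @export
stratified_summaries <- function(results, veh, households,
                                 thresholds = default_thresholds(),
                                 iron_curve = default_iron_risk_curve(),
                                 weighted = TRUE) {
  known <- c("national", "urban", "rural")
  if (!all(nzchar(households$stratum))) abort("unknown stratum label")
  hh <- households
  if (!weighted) hh$weight <- 1

  afe_tab <- dplyr::distinct(results[, c("household_id", "afe")])
  veh_afe <- dplyr::inner_join(veh, afe_tab, by = "household_id")
  veh_afe <- dplyr::inner_join(veh_afe, hh, by = "household_id")
  for (v in VEHICLES) veh_afe[[paste0(v, "_per_afe")]] <- veh_afe[[v]] / veh_afe$afe

  doms <- domain_list(veh_afe)
  coverage <- purrr::map_dfr(names(doms), function(d) {
    sub <- veh_afe[doms[[d]], ]
    if (nrow(sub) == 0) return(NULL)
    purrr::map_dfr(VEHICLES, function(v) {
      tibble::tibble(
        domain = d, vehicle = v, n = nrow(sub),
        coverage_pct = 100 * sum(sub$weight[sub[[v]] > 0]) / sum(sub$weight)
      )
    })
  })
  consumption <- purrr::map_dfr(names(doms), function(d) {
    sub <- veh_afe[doms[[d]], ]
    if (nrow(sub) == 0) return(NULL)
    purrr::map_dfr(VEHICLES, function(v) {
      cons <- sub[sub[[v]] > 0, ]
      x <- cons[[paste0(v, "_per_afe")]]
      if (nrow(cons) == 0) {
        return(tibble::tibble(domain = d, vehicle = v, n_consumers = 0,
                              p25 = NA_real_, median = NA_real_, p75 = NA_real_))
      }
      qs <- weighted_quantile(x, cons$weight, c(0.25, 0.5, 0.75))
      tibble::tibble(domain = d, vehicle = v, n_consumers = nrow(cons),
                     p25 = qs[1], median = qs[2], p75 = qs[3])
    })
  })

  res <- dplyr::inner_join(results, hh, by = "household_id")
  doms_r <- domain_list(res)

  har <- thresholds$har
  inadequacy <- purrr::map_dfr(unique(res$scenario), function(sc) {
    rs <- res[res$scenario == sc, ]
    purrr::map_dfr(names(doms_r), function(d) {
      sub <- rs[doms_r[[d]][res$scenario == sc], ]
      if (nrow(sub) == 0) return(NULL)
      rows <- purrr::map_dfr(names(har), function(n) {
        tibble::tibble(nutrient = n,
                       prevalence_pct = prevalence_inadequate_cutpoint(
                         sub[[n]], sub$weight, har[[n]]))
      })
      rows <- dplyr::bind_rows(
        tibble::tibble(nutrient = "iron_mg",
                       prevalence_pct = prevalence_inadequate_iron(
                         sub$iron_mg, sub$weight, iron_curve)),
        rows)
      rows$scenario <- sc; rows$domain <- d; rows$n <- nrow(sub)
      rows
    })
  })

  excess_spec <- tibble::tribble(
    ~nutrient, ~authority,
    "iron_mg", NA_character_,
    "zinc_mg", "efsa",
    "zinc_mg", "iom",
    "retinol_mcg", NA_character_,
    "folic_acid_mcg", NA_character_
  )
  excess <- purrr::map_dfr(unique(res$scenario), function(sc) {
    rs <- res[res$scenario == sc, ]
    purrr::map_dfr(names(doms_r), function(d) {
      sub <- rs[doms_r[[d]][res$scenario == sc], ]
      if (nrow(sub) == 0) return(NULL)
      rows <- purrr::map_dfr(seq_len(nrow(excess_spec)), function(i) {
        n <- excess_spec$nutrient[i]
        auth <- excess_spec$authority[i]
        tibble::tibble(nutrient = n, authority = auth,
                       prevalence_pct = prevalence_excess(
                         sub[[n]], sub$weight, n, thresholds,
                         zn_authority = if (is.na(auth)) "efsa" else auth))
      })
      rows$scenario <- sc; rows$domain <- d; rows$n <- nrow(sub)
      rows
    })
  })

  gaps <- purrr::map_dfr(unique(res$scenario), function(sc) {
    rs <- res[res$scenario == sc, ]
    purrr::map_dfr(names(doms_r), function(d) {
      sub <- rs[doms_r[[d]][res$scenario == sc], ]
      if (nrow(sub) == 0) return(NULL)
      nut_gap <- purrr::map_dfr(names(har), function(n) {
        tibble::tibble(nutrient = n, gap_type = "micronutrient_gap",
                       gap = micronutrient_gap(sub[[n]], sub$weight, har[[n]]))
      })
      safe_gap <- tibble::tibble(
        nutrient = c("zinc_mg", "zinc_mg"),
        gap_type = c("safety_gap_efsa", "safety_gap_iom"),
        gap = c(safety_gap(sub$zinc_mg, sub$weight, thresholds$hul[["zinc_mg_efsa"]]),
                safety_gap(sub$zinc_mg, sub$weight, thresholds$hul[["zinc_mg_iom"]]))
      )
      rows <- dplyr::bind_rows(nut_gap, safe_gap)
      rows$scenario <- sc; rows$domain <- d; rows$n <- nrow(sub)
      rows
    })
  })

  list(coverage = coverage, consumption = consumption,
       inadequacy = inadequacy, excess = excess, gaps = gaps)
}
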