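# discrete age pyramid of a young population: per-year sampling weights
age_pyramid_weights <- function() {
  band <- tibble::tribble(
    ~lo, ~hi, ~p,
    0, 4, .165, 5, 9, .145, 10, 14, .130, 15, 19, .105, 20, 24, .090,
    25, 29, .075, 30, 34, .065, 35, 39, .055, 40, 44, .045, 45, 49, .035,
    50, 54, .027, 55, 59, .020, 60, 64, .015, 65, 69, .011, 70, 74, .008,
    75, 80, .009
  )
  w <- numeric(81)
  for (i in seq_len(nrow(band))) {
    yrs <- band$lo[i]:band$hi[i]
    w[yrs + 1] <- band$p[i] / length(yrs)
  }
  w
}

# smooth reference body weight (kg) by age and sex, used to draw "measured"
# anthropometry in the generator
default_body_weight <- function(age_y, sex) {
  wm <- c(6, 10, 12.5, 14.5, 16.5, 18.5, 20.5, 23, 25.5, 28.5, 31.5, 35,
          39, 44, 48, 51, 54, 57)
  wf <- c(5.8, 9.5, 12, 14, 16, 18, 20, 22.5, 25, 28.5, 32, 36, 41, 45,
          48, 50, 52, 53)
  idx <- pmin(floor(age_y), 17) + 1
  out <- ifelse(sex == "male", wm[idx], wf[idx])
  out[age_y >= 18 & sex == "male"] <- 61
  out[age_y >= 18 & sex == "female"] <- 56
  out[age_y < 1] <- 3.3 + 0.55 * (age_y[age_y < 1] * 12)
  out
}

rtrunc_norm <- function(n, t) qnorm(runif(n, pnorm(-t), pnorm(t)))

#' Generate a synthetic household survey with known ground truth
#'
#' Draws a stratified cluster sample of households, a member roster with a
#' young-population age pyramid, measured anthropometry for women up to 50
#' and boys up to 15, mother-child links for children below 24 months, and a
#' 7-day food consumption table following the consumption model (coverage,
#' truncated-lognormal quantities scaled by the household's adult female
#' equivalents, reporting units and acquisition sources). Ground truth -
#' per-household per-AFE intakes under every fortification scenario and the
#' survey-weighted true prevalences - is computed from the uncorrupted
#' quantities by an independent straight-line implementation before outliers
#' and missing values are injected.
#'
#' @param design Design from [survey_design()].
#' @param model Consumption model from [default_consumption_model()].
#' @param fixtures Fixture tables from [generate_fixtures()].
#' @param seed Integer seed; identical seeds give identical surveys.
#' @param fortification_spec Parameter table used for the ground-truth
#'   scenario intakes.
#' @param thresholds Threshold set used for ground-truth prevalences.
#' @return List with `households`, `roster`, `consumption` (observed, i.e.
#'   corrupted), `injections` (bookkeeping of injected corruption) and
#'   `ground_truth` (list of `afe`, `base_intakes`, `vehicles`, `intakes`,
#'   `prevalence`).
#' @export
generate_survey <- function(design = survey_design(),
                            model = default_consumption_model(),
                            fixtures = generate_fixtures(),
                            seed = 1L,
                            fortification_spec = default_fortification_spec(),
                            thresholds = default_thresholds()) {
  if (!inherits(design, "hcesfort_design")) abort("design must come from survey_design()",
                                                 class = "hcesfort_config_error")
  items <- model$items
  if (any(items$coverage < 0 | items$coverage > 1)) {
    abort("coverage probabilities must lie in [0,1]", class = "hcesfort_config_error")
  }
  if (model$missing_rate < 0 || model$missing_rate > 1 ||
      model$outlier_rate < 0 || model$outlier_rate > 1) {
    abort("corruption rates must lie in [0,1]", class = "hcesfort_config_error")
  }
  missing_strata <- setdiff(design$strata, unique(items$stratum))
  if (length(missing_strata) > 0) {
    abort(sprintf("consumption model lacks strata: %s",
                  paste(missing_strata, collapse = ", ")),
          class = "hcesfort_config_error")
  }

  withr::with_seed(seed, {
    ## households -----------------------------------------------------------
    hh <- purrr::map_dfr(design$strata, function(s) {
      k <- design$clusters_per_stratum[[s]]
      tibble::tibble(stratum = s,
                     cluster = paste0(s, "-", rep(seq_len(k),
                                                  each = design$households_per_cluster)))
    })
    n <- nrow(hh)
    hh$household_id <- seq_len(n)
    hh$urban <- runif(n) < design$urban_share[hh$stratum]
    n_s <- table(hh$stratum)[design$strata]
    base_w <- design$pop_share / (as.numeric(n_s) / n)
    names(base_w) <- design$strata
    hh$weight <- unname(base_w[hh$stratum]) *
      runif(n, design$weight_noise[1], design$weight_noise[2])
    hh <- hh[, c("household_id", "stratum", "cluster", "urban", "weight")]

    ## roster ---------------------------------------------------------------
    sizes <- pmin(1 + rpois(n, 3.7), 12)
    pyr <- age_pyramid_weights()
    adult_pyr <- replace(pyr, 1:18, 0)
    m <- sum(sizes)
    roster <- tibble::tibble(
      household_id = rep(hh$household_id, sizes),
      member_id = sequence(sizes)
    )
    age <- sample(0:80, m, replace = TRUE, prob = pyr)
    head_row <- roster$member_id == 1
    age[head_row] <- sample(0:80, sum(head_row), replace = TRUE, prob = adult_pyr)
    sex <- sample(c("male", "female"), m, replace = TRUE)
    age_months <- rep(NA_real_, m)
    infant <- age < 2
    age_months[infant] <- age[infant] * 12 + sample(0:11, sum(infant), replace = TRUE)
    roster$age_years <- ifelse(infant, NA_real_, age)
    roster$age_months <- age_months
    roster$sex <- sex
    age_exact <- ifelse(infant, age_months / 12, age)
    measured <- (sex == "female" & age_exact <= 50) | (sex == "male" & age_exact <= 15)
    bw <- default_body_weight(age_exact, sex)
    w_obs <- pmax(2.5, rnorm(m, bw, 0.12 * bw))
    roster$weight_kg <- ifelse(measured, w_obs, NA_real_)

    # mother links for infants: a woman aged 15-49 of the same household
    roster$mother_id <- NA_integer_
    cand <- roster$sex == "female" & age_exact >= 15 & age_exact < 50
    cand_split <- split(roster$member_id[cand], roster$household_id[cand])
    inf_idx <- which(infant)
    for (i in inf_idx) {
      mothers <- cand_split[[as.character(roster$household_id[i])]]
      if (!is.null(mothers) && length(mothers) > 0) {
        roster$mother_id[i] <- if (length(mothers) == 1) mothers else sample(mothers, 1)
      }
    }

    afe_true <- gt_household_afe(roster)

    ## consumption ----------------------------------------------------------
    fl <- fixtures$food_list
    rd <- fixtures$refuse_density
    pt <- fixtures$portions
    afe_vec <- afe_true$afe[match(hh$household_id, afe_true$household_id)]

    cons <- purrr::map_dfr(design$strata, function(s) {
      idx <- which(hh$stratum == s)
      it <- items[items$stratum == s, ]
      purrr::map_dfr(seq_len(nrow(it)), function(j) {
        row <- it[j, ]
        consuming <- idx[runif(length(idx)) < row$coverage]
        nc <- length(consuming)
        if (nc == 0) return(NULL)
        z <- rtrunc_norm(nc, model$trunc_sd)
        gpd_afe <- row$median_gpd_afe * exp(row$sdlog * z)
        grams7 <- gpd_afe * afe_vec[consuming] * 7
        unit <- fl$report_unit[fl$food_code == row$food_code]
        qty <- switch(unit,
          kg = grams7 / 1000,
          g = grams7,
          L = grams7 / (1000 * rd$density_g_ml[rd$food_code == row$food_code]),
          mL = grams7 / rd$density_g_ml[rd$food_code == row$food_code],
          pieces = pmax(1, round(grams7 / pt$portion_g[pt$food_code == row$food_code]))
        )
        tibble::tibble(
          household_id = hh$household_id[consuming],
          food_code = row$food_code,
          quantity = qty,
          unit = unit,
          source = sample(VALID_SOURCES, nc, replace = TRUE,
                          prob = c(row$p_purchase, row$p_own, row$p_gift)),
          stratum = s,
          sdlog = row$sdlog
        )
      })
    })
    cons <- dplyr::arrange(cons, .data$household_id, .data$food_code)

    ## ground truth (pre-corruption) ---------------------------------------
    truth <- gt_compute(hh, roster, cons, fixtures, fortification_spec, thresholds)

    ## corruption injection -------------------------------------------------
    cons$row <- seq_len(nrow(cons))
    grp <- paste(cons$stratum, cons$food_code)
    grp_size <- table(grp)
    eligible <- grp_size[grp] >= model$min_group_injection

    u_out <- runif(nrow(cons))
    cand_out <- which(eligible & u_out < model$outlier_rate)
    # cap injections per group so inflation cannot mask itself
    keep <- unlist(lapply(split(cand_out, grp[cand_out]), function(ix) {
      head(ix, model$max_injections_per_group)
    }), use.names = FALSE)
    out_rows <- sort(keep)

    u_mis <- runif(nrow(cons))
    mis_rows <- which(eligible & u_mis < model$missing_rate &
                        !seq_len(nrow(cons)) %in% out_rows)

    injections <- dplyr::bind_rows(
      tibble::tibble(household_id = cons$household_id[out_rows],
                     food_code = cons$food_code[out_rows],
                     type = "outlier",
                     true_quantity = cons$quantity[out_rows]),
      tibble::tibble(household_id = cons$household_id[mis_rows],
                     food_code = cons$food_code[mis_rows],
                     type = "missing",
                     true_quantity = cons$quantity[mis_rows])
    )

    if (length(out_rows) > 0) {
      infl <- cons$quantity[out_rows] * exp(model$outlier_k * cons$sdlog[out_rows])
      piece <- cons$unit[out_rows] == "pieces"
      infl[piece] <- round(infl[piece])
      cons$quantity[out_rows] <- infl
    }
    if (length(mis_rows) > 0) cons$quantity[mis_rows] <- NA_real_

    consumption <- cons[, c("household_id", "food_code", "quantity", "unit", "source")]

    list(households = hh,
         roster = roster[, c("household_id", "member_id", "age_years", "age_months",
                             "sex", "weight_kg", "mother_id")],
         consumption = consumption,
         injections = injections,
         ground_truth = truth,
         seed = seed)
  })
}
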