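# Synthetic multi-country cohort generator. Emulates the three-table
# structure of a web-based 24-h recall study across 8 countries and 3 age
# groups, with a per-participant latent diversity propensity d and
# injectable effects of d on fruit/vegetable variety (beta_fv), fiber intake
# (beta_fiber), ultra-processed energy share (beta_upf) and adult
# overweight/obesity (beta_obesity). With all betas zero, diet is
# independent of d by construction.

#' Simulation configuration
#'
#' @param seed Integer seed; each table draws from its own stream derived
#'   from this seed by a fixed offset, so any table can be regenerated
#'   independently.
#' @param n_per_age_group Named integer vector `c(child=, teen=, adult=)`.
#'   Defaults total 3035 participants.
#' @param country_weights Eight sampling proportions (normalised internally).
#' @param isced_probs Three proportions for low/medium/high parental
#'   education.
#' @param p_male Probability of male sex.
#' @param catalogue_sizes Named integer vector of foods per group, including
#'   the `excluded` bucket; every size must be positive.
#' @param n_recall_days Recall days per participant (>= 3).
#' @param d_mean,d_sd Mean and SD of the latent diversity propensity d.
#' @param beta_fv Increase in expected distinct fruit+vegetable items (over
#'   the 3 analysis days) per unit d.
#' @param beta_fiber Increase in expected fiber intake (g/day) per unit d,
#'   injected through the daily amount of a high-fiber wholegrain staple.
#' @param beta_upf Shift in ultra-processed (NOVA 4) food selection with d,
#'   in percentage points of UPF energy share per unit d (expected negative).
#' @param beta_obesity High-vs-low log-odds of adult overweight/obesity
#'   across thirds of d (the middle third sits halfway).
#' @param items_per_meal,meals_per_day Mean counts shaping recall volume.
#' @param intake_volume_slope Fractional increase in a participant's meal
#'   slots per unit d. Diverse eaters report more eating occasions and more
#'   energy, which is what makes the variety ratio (distinct/total foods)
#'   fall as diversity rises.
#' @return A validated list of class `dietdiv_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_per_age_group = c(child = 1012, teen = 1012,
                                           adult = 1011),
                       country_weights = rep(1 / 8, 8),
                       isced_probs = c(low = 0.10, medium = 0.252,
                                       high = 0.648),
                       p_male = 0.41,
                       catalogue_sizes = c(cereal = 30, dairy = 25,
                                           fruit = 35, vegetables = 40,
                                           protein_foods = 35,
                                           excluded = 30),
                       n_recall_days = 3,
                       d_mean = 0, d_sd = 1,
                       beta_fv = 2, beta_fiber = 3, beta_upf = -5,
                       beta_obesity = -0.5,
                       items_per_meal = 3, meals_per_day = 4,
                       intake_volume_slope = 0.25) {
  stopifnot(length(n_per_age_group) == 3, all(n_per_age_group >= 0),
            length(country_weights) == 8, all(country_weights >= 0),
            sum(country_weights) > 0,
            length(isced_probs) == 3, all(isced_probs >= 0),
            p_male >= 0, p_male <= 1,
            n_recall_days >= 3, d_sd > 0,
            items_per_meal >= 1, meals_per_day >= 1)
  if (!all(sort(names(catalogue_sizes)) == sort(food_group_levels())) ||
      any(catalogue_sizes < 1)) {
    abort("catalogue_sizes must name every food group with a positive size",
          class = "dietdiv_config_error")
  }
  names(n_per_age_group) <- age_group_levels()
  structure(list(
    seed = as.integer(seed),
    n_per_age_group = n_per_age_group,
    country_weights = country_weights / sum(country_weights),
    isced_probs = isced_probs / sum(isced_probs),
    p_male = p_male,
    catalogue_sizes = catalogue_sizes,
    n_recall_days = as.integer(n_recall_days),
    d_mean = d_mean, d_sd = d_sd,
    beta_fv = beta_fv, beta_fiber = beta_fiber, beta_upf = beta_upf,
    beta_obesity = beta_obesity,
    items_per_meal = items_per_meal, meals_per_day = meals_per_day,
    intake_volume_slope = intake_volume_slope
  ), class = "dietdiv_sim_config")
}

runif_range <- function(n, lo, hi) runif(n, lo, hi)

#' Generate a synthetic food catalogue
#'
#' Foods carry group-typical nutrient profiles (fruits and vegetables have
#' low energy density and positive fiber; the excluded bucket is sugar- or
#' fat-dense and NOVA-4 enriched). Energy is Atwater-consistent
#' (4/9/4 kcal per g of protein/fat/carbohydrate). The first cereal food is
#' a high-fiber wholegrain staple used to inject the fiber effect.
#'
#' @param config A [sim_config()].
#' @return Validated catalogue tibble.
#' @export
generate_catalogue <- function(config) {
  set.seed(config$seed + 11L)
  sizes <- config$catalogue_sizes[food_group_levels()]
  rows <- lapply(food_group_levels(), function(g) {
    n <- sizes[[g]]
    prof <- switch(g,
      cereal = tibble::tibble(
        protein_g = runif_range(n, 7, 13), fat_g = runif_range(n, 1, 6),
        carbohydrate_g = runif_range(n, 45, 72),
        sugar_g = runif_range(n, 1, 5), fiber_g = runif_range(n, 2, 9),
        is_solid = TRUE),
      dairy = tibble::tibble(
        protein_g = runif_range(n, 3, 22), fat_g = runif_range(n, 1, 28),
        carbohydrate_g = runif_range(n, 3, 8),
        sugar_g = runif_range(n, 2, 6), fiber_g = 0,
        is_solid = runif(n) > 0.3),
      fruit = tibble::tibble(
        protein_g = runif_range(n, 0.3, 1.5), fat_g = runif_range(n, 0, 0.5),
        carbohydrate_g = runif_range(n, 6, 20),
        sugar_g = runif_range(n, 4, 6), fiber_g = runif_range(n, 1, 5),
        is_solid = runif(n) > 0.15),
      vegetables = tibble::tibble(
        protein_g = runif_range(n, 1, 3), fat_g = runif_range(n, 0, 0.5),
        carbohydrate_g = runif_range(n, 2, 10),
        sugar_g = runif_range(n, 0.5, 2), fiber_g = runif_range(n, 1.5, 6),
        is_solid = TRUE),
      protein_foods = tibble::tibble(
        protein_g = runif_range(n, 15, 28), fat_g = runif_range(n, 2, 20),
        carbohydrate_g = runif_range(n, 0, 3),
        sugar_g = 0, fiber_g = runif_range(n, 0, 1),
        is_solid = TRUE),
      excluded = tibble::tibble(
        protein_g = runif_range(n, 0, 5), fat_g = runif_range(n, 5, 30),
        carbohydrate_g = runif_range(n, 20, 60),
        sugar_g = runif_range(n, 10, 20), fiber_g = runif_range(n, 0, 1),
        is_solid = runif(n) > 0.35))
    nova_probs <- if (g == "excluded") c(.05, .05, .10, .80) else
      c(.45, .15, .20, .20)
    prof$food_group <- g
    prof$nova_class <- sample(1:4, n, replace = TRUE, prob = nova_probs)
    prof$sugar_g <- pmin(prof$sugar_g, prof$carbohydrate_g)
    prof$sfa_g <- prof$fat_g * runif_range(n, 0.2, 0.6)
    prof
  })
  cat <- dplyr::bind_rows(rows)
  # wholegrain staple: first cereal, fixed high fiber, always solid, minimally
  # processed
  cat$fiber_g[1] <- 10
  cat$is_solid[1] <- TRUE
  cat$nova_class[1] <- 1L
  cat$energy_kcal <- 4 * cat$protein_g + 9 * cat$fat_g +
    4 * cat$carbohydrate_g
  cat$food_code <- sprintf("F%04d", seq_len(nrow(cat)))
  cat$name <- paste0(cat$food_group, "_", seq_len(nrow(cat)))
  # guarantee at least one solid and one beverage
  if (all(cat$is_solid)) cat$is_solid[cat$food_group == "dairy"][1] <- FALSE
  if (!any(cat$is_solid)) cat$is_solid[1] <- TRUE
  validate_catalogue(cat[, catalogue_columns()])
}

staple_code <- function(catalogue) {
  catalogue$food_code[as.character(catalogue$food_group) == "cereal"][1]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate synthetic participants
#'
#' Ages are uniform within each age-group's bounds; the latent diversity
#' propensity d is Normal(d_mean, d_sd) and returned in column `latent_d`
#' (non-observable truth, kept for parameter-recovery tests; it is written to
#' a separate truth file, never to the participant CSV). Adult
#' overweight/obesity odds follow `beta_obesity` across thirds of d, and BMI
#' is drawn consistently with the category; minors receive a BMI z-score and
#' the category rule z < 1 normal, 1 <= z < 2 overweight, z >= 2 obese
#' (standing in for external reference tables). FFQ covariates are noisy
#' monotone functions of d.
#'
#' @param config A [sim_config()].
#' @return Validated participant tibble with extra column `latent_d`.
#' @export
generate_participants <- function(config) {
  set.seed(config$seed + 29L)
  n_grp <- config$n_per_age_group
  n <- sum(n_grp)
  age <- c(runif(n_grp[["child"]], 6, 12), runif(n_grp[["teen"]], 12, 20),
           runif(n_grp[["adult"]], 20, 75))
  d <- rnorm(n, config$d_mean, config$d_sd)
  pp <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    sex = ifelse(runif(n) < config$p_male, "male", "female"),
    age_years = age,
    age_group = as.character(age_group_of(age)),
    country = sample(country_levels(), n, replace = TRUE,
                     prob = config$country_weights),
    isced = sample(isced_levels(), n, replace = TRUE,
                   prob = config$isced_probs),
    latent_d = d
  )

  is_adult <- pp$age_group == "adult"
  pp$bmi_zscore <- NA_real_
  pp$waist_zscore <- NA_real_
  pp$bmi_kg_m2 <- NA_real_
  pp$waist_cm <- NA_real_
  pp$bmi_category <- NA_character_

  if (any(is_adult)) {
    da <- d[is_adult]
    third <- quantile_bin(da, c(1 / 3, 2 / 3))
    # bottom-third log-odds of overweight/obesity ~ logit(0.45); the
    # high-vs-low contrast equals beta_obesity
    lp <- qlogis(0.45) + config$beta_obesity * (third - 1) / 2
    ow_ob <- rbinom(sum(is_adult), 1, plogis(lp)) == 1
    obese <- ow_ob & runif(sum(is_adult)) < 0.3
    bmi <- ifelse(!ow_ob, runif(sum(is_adult), 19, 24.9),
                  ifelse(obese, runif(sum(is_adult), 30, 40),
                         runif(sum(is_adult), 25, 29.9)))
    pp$bmi_kg_m2[is_adult] <- bmi
    pp$bmi_category[is_adult] <-
      as.character(bmi_category_adult(bmi))
    pp$waist_cm[is_adult] <- 2.4 * bmi + rnorm(sum(is_adult), 10, 5)
  }
  if (any(!is_adult)) {
    nm <- sum(!is_adult)
    z <- rnorm(nm, 0.3, 1.1)
    pp$bmi_zscore[!is_adult] <- z
    pp$bmi_category[!is_adult] <-
      ifelse(z < 1, "normal", ifelse(z < 2, "overweight", "obese"))
    agem <- pp$age_years[!is_adult]
    pp$bmi_kg_m2[!is_adult] <- 15 + 0.35 * (agem - 6) + 1.8 * z
    wz <- 0.8 * z + rnorm(nm, 0, 0.6)
    pp$waist_zscore[!is_adult] <- wz
    pp$waist_cm[!is_adult] <- 50 + 2 * (agem - 6) + 5 * wz
  }

  # biomarkers on a subgroup (about 60% have blood values)
  has_blood <- runif(n) < 0.6
  blood <- function(v) ifelse(has_blood, v, NA_real_)
  pp$glucose_mmol_l <- blood(pmax(3, rnorm(n, 4.9, 0.5)))
  pp$insulin_mU_l <- blood(exp(rnorm(n, log(8), 0.4)))
  pp$hba1c_pct <- blood(rnorm(n, 5.2, 0.3))
  pp$triglycerides_mg_dl <- blood(exp(rnorm(n, log(90), 0.35)))
  pp$hdl_mg_dl <- blood(rnorm(n, 55, 12))
  pp$ldl_mg_dl <- blood(rnorm(n, 100, 25))
  pp$sbp_mmHg <- pmax(70, rnorm(n, 100 + 0.4 * pp$age_years, 10))
  pp$dbp_mmHg <- pmax(40, rnorm(n, 60 + 0.15 * pp$age_years, 8))

  # FFQ covariates: noisy monotone in d
  pp$hdas <- clamp(25 + 4 * d + rnorm(n, 0, 4), 0, 50)
  pp$meal_freq_per_day <- pmax(1, 3.5 + 0.3 * d + rnorm(n, 0, 0.5))
  pp$junkfood_freq_per_day <- pmax(0, 1.5 - 0.3 * d + rnorm(n, 0, 0.4))
  pp$fv_freq_per_day <- pmax(0, 2 + 0.5 * d + rnorm(n, 0, 0.6))
  pp$fiberrich_freq_per_day <- pmax(0, 1.5 + 0.4 * d + rnorm(n, 0, 0.5))

  validate_participants(pp)
}

#' Generate synthetic 24-h recall records
#'
#' Each participant-day holds `meals_per_day` occasions of `items_per_meal`
#' foods. The participant's 3-day food repertoire is drawn so that the
#' expected number of distinct fruit+vegetable foods rises by `beta_fv` per
#' unit of latent d (other core groups move at a quarter of that slope, so a
#' null `beta_fv` makes diversity independent of d); NOVA-4 foods are
#' down-weighted in selection as d grows (`beta_upf`); and the daily amount
#' of the wholegrain staple shifts fiber intake by `beta_fiber` g/day per
#' unit d.
#'
#' @param participants Participant tibble from [generate_participants()]
#'   (must carry `latent_d`).
#' @param catalogue Catalogue from [generate_catalogue()].
#' @param config The same [sim_config()].
#' @return Validated recall tibble.
#' @export
generate_recalls <- function(participants, catalogue, config) {
  if (!"latent_d" %in% names(participants)) {
    abort("participants must carry the latent_d column",
          class = "dietdiv_config_error")
  }
  set.seed(config$seed + 47L)
  n <- nrow(participants)
  d <- participants$latent_d
  groups <- dds_food_groups()
  base_k <- c(cereal = 5, dairy = 4, fruit = 4, protein_foods = 4,
              vegetables = 5)
  slope_k <- c(cereal = config$beta_fv / 4, dairy = config$beta_fv / 4,
               fruit = config$beta_fv / 2,
               protein_foods = config$beta_fv / 4,
               vegetables = config$beta_fv / 2)
  mean_amt <- c(cereal = 80, dairy = 150, fruit = 120, protein_foods = 110,
                vegetables = 100, excluded = 60)

  cat_group <- as.character(catalogue$food_group)
  pools <- split(seq_len(nrow(catalogue)), cat_group)
  staple_ix <- pools[["cereal"]][1]
  staple_fiber_per_g <- catalogue$fiber_g[staple_ix] / 100

  n_days <- config$n_recall_days
  base_slots <- n_days * round(config$meals_per_day) *
    round(config$items_per_meal)
  # NOVA-4 selection weight per participant
  w4 <- exp((config$beta_upf / 10) * d)
  # intake volume (meal slots) grows with d
  slots_i <- pmax(n_days * 2, round(base_slots *
    (1 + config$intake_volume_slope * d + rnorm(n, 0, 0.1))))

  per_participant <- vector("list", n)
  for (i in seq_len(n)) {
    picks <- integer(0)
    for (g in groups) {
      pool <- pools[[g]]
      if (g == "cereal") pool <- setdiff(pool, staple_ix)
      k <- round(base_k[[g]] + slope_k[[g]] * d[i] + rnorm(1, 0, 0.5))
      k <- clamp(k, 1, length(pool))
      w <- ifelse(catalogue$nova_class[pool] == 4L, w4[i], 1)
      picks <- c(picks, sample(pool, k, prob = w))
    }
    pool_ex <- pools[["excluded"]]
    k_ex <- clamp(round(3 + rnorm(1, 0, 0.8)), 0, length(pool_ex))
    if (k_ex > 0) {
      w <- ifelse(catalogue$nova_class[pool_ex] == 4L, w4[i], 1)
      picks <- c(picks, sample(pool_ex, k_ex, prob = w))
    }
    n_rows <- max(slots_i[i], length(picks) + n_days)
    # staple once per day; every picked food at least once; repeats fill the
    # remaining meal slots (staple excluded so its daily amount stays the
    # fiber-injection handle)
    fill <- if (n_rows - n_days - length(picks) > 0) {
      sample(picks, n_rows - n_days - length(picks), replace = TRUE)
    } else integer(0)
    food_ix <- c(rep(staple_ix, n_days), picks, fill)
    is_staple <- food_ix == staple_ix
    day <- integer(length(food_ix))
    day[seq_len(n_days)] <- seq_len(n_days)
    day[-seq_len(n_days)] <- sample(rep_len(seq_len(n_days),
                                            length(food_ix) - n_days))
    per_participant[[i]] <- list(food_ix = food_ix, day = day,
                                 is_staple = is_staple)
  }

  lens <- vapply(per_participant, function(x) length(x$food_ix), integer(1))
  food_ix <- unlist(lapply(per_participant, `[[`, "food_ix"))
  day <- unlist(lapply(per_participant, `[[`, "day"))
  is_staple <- unlist(lapply(per_participant, `[[`, "is_staple"))
  pid <- rep(participants$participant_id, lens)
  d_row <- rep(d, lens)

  grp_row <- cat_group[food_ix]
  amount <- exp(rnorm(length(food_ix), log(mean_amt[grp_row]), 0.4))
  staple_amt <- pmax(20, 150 + config$beta_fiber * d_row / staple_fiber_per_g)
  amount[is_staple] <- staple_amt[is_staple]

  meals <- c("breakfast", "lunch", "dinner", "snack")
  occasion <- meals[1 + (seq_along(food_ix) %% length(meals))]
  rec <- tibble::tibble(
    participant_id = pid,
    recall_index = day,
    recall_date = as.Date("2014-03-03") + 4L * (day - 1L),
    food_code = catalogue$food_code[food_ix],
    amount_g = amount,
    meal_occasion = occasion
  )
  rec <- rec[order(rec$participant_id, rec$recall_index), ]
  validate_recalls(rec, catalogue)
}

#' Simulate a full synthetic cohort
#'
#' Runs [generate_catalogue()], [generate_participants()] and
#' [generate_recalls()] under one configuration. The latent diversity
#' propensity is split out into a `truth` table; the participant table
#' returned is observation-only.
#'
#' @param config A [sim_config()].
#' @return List of class `dietdiv_cohort`: `catalogue`, `participants`,
#'   `recalls`, `truth` (participant_id, d) and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  catalogue <- generate_catalogue(config)
  pp <- generate_participants(config)
  recalls <- generate_recalls(pp, catalogue, config)
  truth <- tibble::tibble(participant_id = pp$participant_id,
                          d = pp$latent_d)
  pp$latent_d <- NULL
  structure(list(catalogue = catalogue, participants = pp,
                 recalls = recalls, truth = truth, config = config),
            class = "dietdiv_cohort")
}

#' Write a simulated cohort to CSV
#'
#' Writes `foods.csv`, `participants.csv`, `recalls.csv` and `truth.csv`
#' (the non-observable latent propensity) under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_food_catalogue(cohort$catalogue, file.path(dir, "foods.csv"))
  write_participants(cohort$participants, file.path(dir, "participants.csv"))
  write_recalls(cohort$recalls, file.path(dir, "recalls.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"),
                   progress = FALSE)
  invisible(dir)
}
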