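# Diet-quality and health-marker derivations: energy and %TEI macronutrients,
# fiber, dietary energy density (solid foods only), ultra-processed-food
# energy share and age-and-sex-specific quintiles, FFQ propensity ratios,
# HOMA-IR, adult BMI categories.

#' Per-participant diet-quality profiles
#'
#' Computes, for every included participant, daily nutrient totals
#' (sum of amount_g x per-100 g composition) averaged over the analysis
#' recall days, energy shares via Atwater factors (4/9/4 kcal per g of
#' protein/fat/carbohydrate; sugar and SFA as sub-shares of carbohydrate and
#' fat energy), fiber in g/day, dietary energy density (mean daily energy
#' from solid foods divided by mean daily grams of solid foods), and the
#' percent of total energy from NOVA class 4 (ultra-processed) foods.
#'
#' @param recalls Validated recall table; the first `min_days` days are used.
#' @param catalogue Validated catalogue.
#' @param min_days Analysis recall days (default 3).
#' @return Tibble with one row per participant: `energy_kcal_day`,
#'   `protein_pct_tei`, `fat_pct_tei`, `sfa_pct_tei`, `carb_pct_tei`,
#'   `sugar_pct_tei`, `fiber_g_day`, `energy_density_kcal_per_g` (NA when no
#'   solid food was consumed), `upf_pct_tei`.
#' @export
diet_quality_profiles <- function(recalls, catalogue, min_days = 3) {
  sel <- select_analysis_recalls(recalls, min_days)
  df <- dplyr::left_join(
    sel,
    catalogue[, c("food_code", "energy_kcal", "protein_g", "fat_g", "sfa_g",
                  "carbohydrate_g", "sugar_g", "fiber_g", "is_solid",
                  "nova_class")],
    by = "food_code")
  # row-level intakes; names must not collide with the summary columns below
  # (summarise evaluates sequentially and new columns mask old ones)
  sc <- df$amount_g / 100
  df$energy_row <- sc * df$energy_kcal
  df$protein_row <- sc * df$protein_g
  df$fat_row <- sc * df$fat_g
  df$sfa_row <- sc * df$sfa_g
  df$carb_row <- sc * df$carbohydrate_g
  df$sugar_row <- sc * df$sugar_g
  df$fiber_row <- sc * df$fiber_g

  n_days <- dplyr::summarise(
    dplyr::group_by(df, .data$participant_id),
    n_days = dplyr::n_distinct(.data$recall_index), .groups = "drop")

  tot <- dplyr::summarise(
    dplyr::group_by(df, .data$participant_id),
    energy = sum(.data$energy_row), protein = sum(.data$protein_row),
    fat = sum(.data$fat_row), sfa = sum(.data$sfa_row),
    carb = sum(.data$carb_row),
    sugar = sum(.data$sugar_row), fiber = sum(.data$fiber_row),
    solid_energy = sum(.data$energy_row[.data$is_solid]),
    solid_grams = sum(.data$amount_g[.data$is_solid]),
    upf_energy = sum(.data$energy_row[.data$nova_class == 4L]),
    .groups = "drop")
  tot <- dplyr::left_join(tot, n_days, by = "participant_id")
  if (any(tot$energy <= 0)) {
    stop_validation(sprintf(
      "zero total energy for participant(s): %s",
      paste(tot$participant_id[tot$energy <= 0], collapse = ", ")))
  }
  tibble::tibble(
    participant_id = tot$participant_id,
    energy_kcal_day = tot$energy / tot$n_days,
    protein_pct_tei = 100 * 4 * tot$protein / tot$energy,
    fat_pct_tei = 100 * 9 * tot$fat / tot$energy,
    sfa_pct_tei = 100 * 9 * tot$sfa / tot$energy,
    carb_pct_tei = 100 * 4 * tot$carb / tot$energy,
    sugar_pct_tei = 100 * 4 * tot$sugar / tot$energy,
    fiber_g_day = tot$fiber / tot$n_days,
    energy_density_kcal_per_g = ifelse(tot$solid_grams > 0,
                                       tot$solid_energy / tot$solid_grams,
                                       NA_real_),
    upf_pct_tei = 100 * tot$upf_energy / tot$energy
  )
}

#' Age- and sex-specific UPF quintiles
#'
#' Splits the ultra-processed-food energy share into quintiles within each
#' age group x sex stratum (cutpoints at the 20/40/60/80th percentiles,
#' right-closed bins, same quantile rule as the diversity scores).
#'
#' @param profiles Output of [diet_quality_profiles()].
#' @param participants Validated participant table.
#' @return `profiles` with an added integer `upf_quintile` column (1--5).
#' @export
upf_quintiles <- function(profiles, participants) {
  df <- dplyr::left_join(
    profiles,
    participants[, c("participant_id", "age_group", "sex")],
    by = "participant_id")
  df$upf_quintile <- NA_integer_
  strata <- interaction(df$age_group, df$sex, drop = TRUE)
  for (s in levels(strata)) {
    ix <- strata == s
    if (sum(ix) < 5) {
      stop_validation(sprintf(
        "stratum '%s' has %d participant(s); need >= 5 for quintiles",
        s, sum(ix)))
    }
    df$upf_quintile[ix] <- quantile_bin(df$upf_pct_tei[ix],
                                        c(.2, .4, .6, .8))
  }
  df[, c(names(profiles), "upf_quintile")]
}

#' FFQ consumption propensity
#'
#' Share of weekly FFQ frequency contributed by flagged (e.g. sugar-rich or
#' fat-rich) items: sum of flagged frequencies over the total frequency of
#' all items assessed.
#'
#' @param weekly_freqs Numeric vector of weekly consumption frequencies.
#' @param rich_flags Logical vector marking the flagged items.
#' @return Propensity in `[0, 1]`.
#' @export
ffq_propensity <- function(weekly_freqs, rich_flags) {
  stopifnot(length(weekly_freqs) == length(rich_flags))
  if (any(weekly_freqs < 0)) stop_validation("frequencies must be >= 0")
  total <- sum(weekly_freqs)
  if (total <= 0) stop_validation("total FFQ frequency must be > 0")
  sum(weekly_freqs[rich_flags]) / total
}

#' HOMA-IR insulin resistance index
#'
#' Fasting blood glucose (mmol/L) times plasma insulin (mU/L), divided by
#' 22.5.
#'
#' @param glucose_mmol_l Fasting glucose in mmol/L.
#' @param insulin_mU_l Fasting insulin in mU/L.
#' @return HOMA-IR (vectorised).
#' @export
homa_ir <- function(glucose_mmol_l, insulin_mU_l) {
  if (any(glucose_mmol_l < 0, na.rm = TRUE) ||
      any(insulin_mU_l < 0, na.rm = TRUE)) {
    stop_validation("glucose and insulin must be >= 0")
  }
  glucose_mmol_l * insulin_mU_l / 22.5
}

#' Adult BMI category
#'
#' Normal below 25 kg/m2, overweight from 25 to below 30, obese from 30.
#' (Minors are categorised by external reference tables and carry their
#' category as an input.)
#'
#' @param bmi_kg_m2 BMI in kg/m2, > 0.
#' @return Factor with levels normal/overweight/obese (vectorised).
#' @export
bmi_category_adult <- function(bmi_kg_m2) {
  if (any(bmi_kg_m2 <= 0, na.rm = TRUE)) {
    stop_validation("BMI must be positive")
  }
  cut(bmi_kg_m2, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = bmi_category_levels())
}
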