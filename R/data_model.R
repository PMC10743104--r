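# The three-table data model: food catalogue, recall records, participants.
# Validators normalise column types, enforce the invariants, and attach a
# class tag so downstream functions can assume a checked table.

catalogue_columns <- function() {
  c("food_code", "name", "food_group", "nova_class", "energy_kcal",
    "protein_g", "fat_g", "sfa_g", "carbohydrate_g", "sugar_g", "fiber_g",
    "is_solid")
}

recall_columns <- function() {
  c("participant_id", "recall_index", "recall_date", "food_code",
    "amount_g", "meal_occasion")
}

participant_columns <- function() {
  c("participant_id", "sex", "age_years", "age_group", "country", "isced",
    "bmi_kg_m2", "bmi_zscore", "waist_cm", "waist_zscore", "bmi_category",
    "glucose_mmol_l", "insulin_mU_l", "hba1c_pct", "triglycerides_mg_dl",
    "hdl_mg_dl", "ldl_mg_dl", "sbp_mmHg", "dbp_mmHg",
    "hdas", "meal_freq_per_day", "junkfood_freq_per_day", "fv_freq_per_day",
    "fiberrich_freq_per_day")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Validate a food catalogue
#'
#' Checks uniqueness of food codes, the food-group vocabulary, NOVA classes
#' in 1--4, non-negative per-100 g composition and macronutrient mass not
#' exceeding 100 g per 100 g.
#'
#' @param catalogue Data frame with the catalogue columns (see
#'   [read_food_catalogue()]).
#' @return The catalogue as a validated tibble.
#' @export
validate_catalogue <- function(catalogue) {
  require_columns(catalogue, catalogue_columns(), "food catalogue")
  cat <- tibble::as_tibble(catalogue)
  dup <- unique(cat$food_code[duplicated(cat$food_code)])
  if (length(dup) > 0) {
    stop_validation(sprintf("duplicate food_code(s): %s",
                            paste(dup, collapse = ", ")))
  }
  bad_group <- setdiff(unique(as.character(cat$food_group)),
                       food_group_levels())
  if (length(bad_group) > 0) {
    stop_validation(sprintf("unknown food_group label(s): %s",
                            paste(bad_group, collapse = ", ")))
  }
  cat$food_group <- factor(as.character(cat$food_group),
                           levels = food_group_levels())
  if (!all(cat$nova_class %in% 1:4)) {
    stop_validation("nova_class must be an integer in 1..4")
  }
  comp <- c("energy_kcal", "protein_g", "fat_g", "sfa_g", "carbohydrate_g",
            "sugar_g", "fiber_g")
  for (col in comp) {
    v <- cat[[col]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_validation(sprintf("negative or non-finite value in '%s'", col))
    }
  }
  if (any(cat$protein_g + cat$fat_g + cat$carbohydrate_g > 100 + 1e-9)) {
    stop_validation("protein_g + fat_g + carbohydrate_g exceeds 100 g/100 g")
  }
  if (any(cat$sfa_g > cat$fat_g + 1e-9)) {
    stop_validation("sfa_g exceeds fat_g")
  }
  if (any(cat$sugar_g > cat$carbohydrate_g + 1e-9)) {
    stop_validation("sugar_g exceeds carbohydrate_g")
  }
  cat$is_solid <- as.logical(cat$is_solid)
  cat$nova_class <- as.integer(cat$nova_class)
  class(cat) <- c("dietdiv_catalogue", class(cat))
  cat
}

#' Validate a recall table
#'
#' Checks that all food codes resolve in the catalogue (strict mode) or drops
#' unresolved rows with a message (lenient mode), that amounts are positive
#' and finite, and that each participant's recall indices are dense from 1
#' in chronological order.
#'
#' @param recalls Data frame of recall rows.
#' @param catalogue Validated catalogue the codes must resolve in.
#' @param unknown_codes `"strict"` (default) to fail on unresolved food
#'   codes, `"lenient"` to drop them with a logged count.
#' @return Validated tibble of recall rows.
#' @export
validate_recalls <- function(recalls, catalogue,
                             unknown_codes = c("strict", "lenient")) {
  unknown_codes <- match.arg(unknown_codes)
  require_columns(recalls, recall_columns(), "recall table")
  rec <- tibble::as_tibble(recalls)
  if (any(!is.finite(rec$amount_g)) || any(rec$amount_g <= 0)) {
    stop_validation("amount_g must be finite and > 0 for every recall row")
  }
  unknown <- setdiff(unique(rec$food_code), catalogue$food_code)
  if (length(unknown) > 0) {
    if (unknown_codes == "strict") {
      stop_validation(sprintf(
        "recall rows reference food code(s) absent from the catalogue: %s",
        paste(unknown, collapse = ", ")))
    }
    n_drop <- sum(rec$food_code %in% unknown)
    inform(sprintf("dropping %d recall row(s) with unknown food codes (%s)",
                   n_drop, paste(unknown, collapse = ", ")))
    rec <- rec[!rec$food_code %in% unknown, , drop = FALSE]
  }
  rec$recall_index <- as.integer(rec$recall_index)
  dense <- vapply(split(rec$recall_index, rec$participant_id), function(ix) {
    days <- sort(unique(ix))
    identical(days, seq_along(days))
  }, logical(1))
  if (!all(dense)) {
    stop_validation(sprintf(
      "recall_index not dense from 1 for participant(s): %s",
      paste(names(dense)[!dense], collapse = ", ")))
  }
  class(rec) <- c("dietdiv_recalls", class(rec))
  rec
}

#' Validate a participant table
#'
#' Enforces the enum vocabularies (sex, age group, country, ISCED, BMI
#' category), consistency of `age_group` with `age_years`, and HDAS in
#' 0--50. Biomarkers and FFQ covariates may be missing (`NA`).
#'
#' @param participants Data frame of participants.
#' @return Validated tibble.
#' @export
validate_participants <- function(participants) {
  require_columns(participants, participant_columns(), "participant table")
  pp <- tibble::as_tibble(participants)
  if (anyDuplicated(pp$participant_id)) {
    stop_validation("duplicate participant_id")
  }
  if (!all(pp$sex %in% c("female", "male"))) {
    stop_validation("sex must be 'female' or 'male'")
  }
  if (!all(pp$country %in% country_levels())) {
    stop_validation("unknown country label")
  }
  if (!all(pp$isced %in% isced_levels())) {
    stop_validation("isced must be low/medium/high")
  }
  expected <- as.character(age_group_of(pp$age_years))
  if (!all(as.character(pp$age_group) == expected)) {
    stop_validation("age_group inconsistent with age_years")
  }
  ok_cat <- is.na(pp$bmi_category) | pp$bmi_category %in% bmi_category_levels()
  if (!all(ok_cat)) stop_validation("unknown bmi_category label")
  hd <- pp$hdas[!is.na(pp$hdas)]
  if (any(hd < 0 | hd > 50)) stop_validation("hdas must lie in [0, 50]")
  pp$age_group <- factor(as.character(pp$age_group),
                         levels = age_group_levels())
  pp$country <- factor(as.character(pp$country), levels = country_levels())
  pp$isced <- factor(as.character(pp$isced), levels = isced_levels())
  pp$sex <- factor(as.character(pp$sex), levels = c("female", "male"))
  class(pp) <- c("dietdiv_participants", class(pp))
  pp
}
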