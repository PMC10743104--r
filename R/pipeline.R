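# End-to-end orchestration: simulate (or read) the three tables, select the
# analysis recalls, score diversity, derive diet-quality profiles, and write
# the association surface (marginal-mean tables and logistic odds ratios)
# plus a JSON run manifest. Outputs are deterministic given the config, so a
# rerun with the same seed reproduces the bundle byte for byte.

quality_outcomes <- function() {
  c("energy_kcal_day", "protein_pct_tei", "fat_pct_tei", "sfa_pct_tei",
    "carb_pct_tei", "sugar_pct_tei", "fiber_g_day",
    "energy_density_kcal_per_g", "upf_pct_tei", "hdas",
    "meal_freq_per_day", "junkfood_freq_per_day", "fv_freq_per_day",
    "fiberrich_freq_per_day")
}

health_outcomes <- function() {
  c("bmi_kg_m2", "bmi_zscore", "waist_cm", "waist_zscore", "homa_ir",
    "hba1c_pct", "glucose_mmol_l", "triglycerides_mg_dl", "hdl_mg_dl",
    "ldl_mg_dl", "sbp_mmHg", "dbp_mmHg")
}

round_cols <- function(df, cols, digits) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], digits)
  df
}

#' Run the full diversity-association pipeline
#'
#' Either simulates a cohort from `config` or reads `foods.csv`,
#' `participants.csv` and `recalls.csv` from `input_dir`, then: selects each
#' participant's first 3 recall days, computes DDS/FVS and tertiles, derives
#' diet-quality profiles and UPF quintiles, computes per-age-group
#' association tables (marginal means + Bonferroni flags) for diet-quality
#' and health outcomes against both indices, and fits adjusted logistic
#' models of overweight/obesity on the tertiles (model a: sex, age, country,
#' ISCED; model b: + energy). All tables are written as CSV under `out_dir`
#' together with an exclusion report and a JSON manifest echoing the
#' configuration.
#'
#' @param config A [sim_config()] used when `input_dir` is NULL.
#' @param input_dir Optional directory with the three input CSVs.
#' @param out_dir Output directory.
#' @param min_days Analysis recall days (default 3).
#' @param adjusted Covariates for the marginal-mean tables (default
#'   unadjusted, the descriptive mode; pass e.g.
#'   `c("sex", "age_years", "country", "isced", "bmi_kg_m2")` for the
#'   adjusted mode).
#' @return Invisibly, a list with all result tables.
#' @export
run_pipeline <- function(config = sim_config(), input_dir = NULL,
                         out_dir, min_days = 3, adjusted = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(input_dir)) {
    cohort <- simulate_cohort(config)
    catalogue <- cohort$catalogue
    participants <- cohort$participants
    recalls <- cohort$recalls
  } else {
    catalogue <- read_food_catalogue(file.path(input_dir, "foods.csv"))
    participants <- read_participants(file.path(input_dir,
                                                "participants.csv"))
    recalls <- read_recalls(file.path(input_dir, "recalls.csv"), catalogue)
  }

  scores <- score_diversity(recalls, catalogue, participants,
                            min_days = min_days)
  exclusions <- attr(scores, "exclusions")
  profiles <- diet_quality_profiles(recalls, catalogue, min_days = min_days)
  profiles <- upf_quintiles(profiles, participants)

  # scores carries age_group too; keep the participant table's copy
  analysis <- dplyr::left_join(scores[, setdiff(names(scores), "age_group")],
                               profiles, by = "participant_id")
  analysis <- dplyr::left_join(analysis, participants, by = "participant_id")
  analysis$homa_ir <- homa_ir(analysis$glucose_mmol_l,
                              analysis$insulin_mU_l)

  assoc <- dplyr::bind_rows(
    association_table(analysis, quality_outcomes(), "dds_tertile", "DDS",
                      covariates = adjusted),
    association_table(analysis, quality_outcomes(), "fvs_tertile", "FVS",
                      covariates = adjusted))
  health <- dplyr::bind_rows(
    association_table(analysis, intersect(health_outcomes(),
                                          names(analysis)[colSums(!is.na(
                                            analysis)) > 0]),
                      "dds_tertile", "DDS", covariates = adjusted),
    association_table(analysis, intersect(health_outcomes(),
                                          names(analysis)[colSums(!is.na(
                                            analysis)) > 0]),
                      "fvs_tertile", "FVS", covariates = adjusted))

  logistic <- list()
  for (ag in intersect(age_group_levels(),
                       unique(as.character(analysis$age_group)))) {
    sub <- analysis[as.character(analysis$age_group) == ag, ]
    for (idx in c(DDS = "dds_tertile", FVS = "fvs_tertile")) {
      for (mod in c("a", "b")) {
        res <- tryCatch(
          fit_overweight_logistic(sub, idx, model = mod),
          dietdiv_validation_error = function(e) NULL)
        if (!is.null(res)) {
          res$age_group <- ag
          res$index <- if (idx == "dds_tertile") "DDS" else "FVS"
          logistic[[length(logistic) + 1]] <- res
        }
      }
    }
  }
  logistic <- dplyr::bind_rows(logistic)

  scores_out <- round_cols(scores, grep("^ratio_", names(scores),
                                        value = TRUE), 4)
  scores_out$fvs <- round(scores_out$fvs, 2)
  readr::write_csv(scores_out, file.path(out_dir, "scores.csv"),
                   progress = FALSE)
  quality_out <- round_cols(profiles, grep("pct_tei$", names(profiles),
                                           value = TRUE), 1)
  readr::write_csv(quality_out, file.path(out_dir, "quality.csv"),
                   progress = FALSE)
  readr::write_csv(assoc, file.path(out_dir, "diet_quality_by_tertile.csv"),
                   progress = FALSE)
  readr::write_csv(health, file.path(out_dir, "health_by_tertile.csv"),
                   progress = FALSE)
  readr::write_csv(logistic, file.path(out_dir, "logistic_odds_ratios.csv"),
                   progress = FALSE)
  readr::write_csv(exclusions, file.path(out_dir, "exclusions.csv"),
                   progress = FALSE)

  manifest <- list(
    seed = if (is.null(input_dir)) config$seed else NA,
    simulated = is.null(input_dir),
    n_participants_included = nrow(scores),
    n_excluded = nrow(exclusions),
    min_days = min_days,
    adjusted_covariates = adjusted,
    config = if (is.null(input_dir)) unclass(config) else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(scores = scores, profiles = profiles,
                 diet_quality_table = assoc, health_table = health,
                 logistic = logistic, exclusions = exclusions,
                 analysis = analysis))
}
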