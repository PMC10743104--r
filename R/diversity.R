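# Dietary diversity score (DDS) and food variety score (FVS).
#
# DDS: within each age group and each of five food groups (cereal, dairy,
# fruit, vegetables, protein foods), the participant's count of distinct
# foods over the 3 analysis days is divided by the distinct-food total of
# that group across the whole age group; age-specific quartiles of these
# ratios receive 1.5/3/4.5/6 points, and the five group scores sum to the
# DDS (range 7.5-30). FVS: distinct foods over total foods consumed by the
# participant over the first 3 days, all food groups included.

#' Count a participant's distinct foods in one group
#'
#' Number of distinct food codes of `food_group` the participant consumed
#' over the selected recall days. Multiplicity and amount are ignored: the
#' same code on different days or occasions is one item.
#'
#' @param recalls Selected (3-day) recall table.
#' @param catalogue Validated catalogue supplying food groups.
#' @param participant_id Single participant id present in `recalls`.
#' @param food_group One of the five DDS food groups.
#' @return Integer count (0 if the participant ate nothing in the group).
#' @export
count_individual_items <- function(recalls, catalogue, participant_id,
                                   food_group) {
  stopifnot(food_group %in% dds_food_groups())
  if (!participant_id %in% recalls$participant_id) {
    stop_validation(sprintf("unknown participant '%s'", participant_id))
  }
  codes <- catalogue$food_code[as.character(catalogue$food_group) ==
                                 food_group]
  rows <- recalls$participant_id == participant_id &
    recalls$food_code %in% codes
  length(unique(recalls$food_code[rows]))
}

#' Distinct foods of a group consumed by an age group
#'
#' The DDS denominator ("total study items"): distinct food codes of
#' `food_group` consumed by any participant of `age_group`.
#'
#' @param recalls Selected recall table restricted to included participants.
#' @param catalogue Validated catalogue.
#' @param participants Validated participant table (supplies age groups).
#' @param age_group One of child/teen/adult.
#' @param food_group One of the five DDS food groups.
#' @return Integer count.
#' @export
compute_total_study_items <- function(recalls, catalogue, participants,
                                      age_group, food_group) {
  stopifnot(food_group %in% dds_food_groups(),
            age_group %in% age_group_levels())
  ids <- participants$participant_id[
    as.character(participants$age_group) == age_group]
  if (length(intersect(ids, recalls$participant_id)) == 0) {
    stop_validation(sprintf("no participant with recalls in age group '%s'",
                            age_group))
  }
  codes <- catalogue$food_code[as.character(catalogue$food_group) ==
                                 food_group]
  rows <- recalls$participant_id %in% ids & recalls$food_code %in% codes
  length(unique(recalls$food_code[rows]))
}

#' Group diversity ratio
#'
#' Exact quotient of a participant's distinct items over the age-group-wide
#' distinct-item total for one food group; no internal rounding (outputs
#' print it at 4 decimals).
#'
#' @param individual_items Integer count, `0 <= individual_items <=
#'   total_study_items`.
#' @param total_study_items Positive integer denominator.
#' @return The ratio in `[0, 1]`.
#' @export
compute_group_ratio <- function(individual_items, total_study_items) {
  if (any(total_study_items < 1)) {
    stop_validation("total_study_items must be >= 1")
  }
  if (any(individual_items < 0 | individual_items > total_study_items)) {
    stop_validation("individual_items must lie in [0, total_study_items]")
  }
  individual_items / total_study_items
}

#' Quartile points for group diversity ratios
#'
#' Assigns each participant's ratio to an age-specific quartile and the
#' corresponding points: first quartile 1.5, second 3, third 4.5, fourth 6.
#' Cutpoints are the empirical 25th/50th/75th percentiles (linear
#' interpolation); bins are right-closed so ties share the lower bin and the
#' all-equal case maps to 1.5 points.
#'
#' @param ratios Named numeric vector of ratios for all participants of one
#'   age group in one food group.
#' @return Tibble with `participant_id`, `quartile` (1--4) and
#'   `fg_dds_score` in {1.5, 3, 4.5, 6}.
#' @export
assign_fg_scores <- function(ratios) {
  if (length(ratios) < 4) {
    stop_validation(paste(
      "fewer than 4 participants in the age group; quartile scoring is",
      "degenerate - pool age groups or supply an explicit override"))
  }
  q <- quantile_bin(ratios, c(.25, .5, .75))
  tibble::tibble(
    participant_id = names(ratios) %||% as.character(seq_along(ratios)),
    quartile = q,
    fg_dds_score = 1.5 * q
  )
}

#' Sum the five group scores into a DDS
#'
#' @param fg_scores Numeric vector of exactly five per-group scores, each in
#'   {1.5, 3, 4.5, 6}. A participant consuming nothing in a group still has
#'   ratio 0 and hence a score; a missing score is an error.
#' @return The DDS (7.5 to 30 in steps of 1.5).
#' @export
compute_dds <- function(fg_scores) {
  if (length(fg_scores) != 5 || any(is.na(fg_scores))) {
    stop_validation("compute_dds needs exactly five non-missing group scores")
  }
  if (!all(fg_scores %in% c(1.5, 3, 4.5, 6))) {
    stop_validation("each group score must be one of 1.5, 3, 4.5, 6")
  }
  sum(fg_scores)
}

#' Food variety score for one participant
#'
#' Distinct food codes divided by total foods consumed (every recall row
#' counts, with multiplicity) over the selected 3 days; all food groups
#' enter, including the excluded-from-DDS bucket.
#'
#' @param recalls Selected recall table.
#' @param participant_id Single participant id.
#' @return List with `individual_items`, `total_individual_items` and `fvs`.
#' @export
compute_fvs <- function(recalls, participant_id) {
  codes <- recalls$food_code[recalls$participant_id == participant_id]
  if (length(codes) == 0) {
    stop_validation(sprintf("participant '%s' consumed no foods",
                            participant_id))
  }
  list(
    individual_items = length(unique(codes)),
    total_individual_items = length(codes),
    fvs = length(unique(codes)) / length(codes)
  )
}

#' Tertile assignment
#'
#' Splits scores at their 33.3rd/66.7th percentiles into low/medium/high,
#' right-closed bins (ties share the lower bin). If all values are identical
#' every participant is labelled low, with a warning.
#'
#' @param values Named numeric vector of scores (one age group, or the whole
#'   cohort when tertiles are not age-stratified).
#' @return Factor of tertile labels, named like `values`.
#' @export
assign_tertiles <- function(values) {
  if (length(values) < 3) {
    stop_validation("need at least 3 participants to form tertiles")
  }
  if (diff(range(values)) == 0) {
    warn("all values identical; assigning every participant to 'low'")
  }
  bins <- quantile_bin(values, c(1 / 3, 2 / 3))
  out <- factor(tertile_levels()[bins], levels = tertile_levels())
  names(out) <- names(values)
  out
}

#' Score dietary diversity for a cohort
#'
#' Runs the full DDS/FVS computation: selects the first `min_days` recall
#' days, counts distinct items per participant and food group, forms
#' age-group-wide totals and ratios, assigns age-specific quartile points,
#' sums them into the DDS, computes the FVS, and assigns tertiles.
#'
#' @param recalls Validated recall table (selection is applied internally;
#'   passing an already-selected table is fine - selection is idempotent).
#' @param catalogue Validated catalogue.
#' @param participants Validated participant table.
#' @param min_days Number of analysis recall days (default 3).
#' @param tertiles_by_age_group Compute DDS/FVS tertile cutpoints within age
#'   group (default) or over the whole cohort.
#' @return Tibble with one row per included participant: the five per-group
#'   ratio and score columns, `dds`, `dds_tertile`, `individual_items_all`,
#'   `total_individual_items`, `fvs`, `fvs_tertile`. Exclusions from day
#'   selection are attached as attribute `"exclusions"`.
#' @export
score_diversity <- function(recalls, catalogue, participants, min_days = 3,
                            tertiles_by_age_group = TRUE) {
  sel <- select_analysis_recalls(recalls, min_days)
  exclusions <- attr(sel, "exclusions")
  pp <- participants[participants$participant_id %in% sel$participant_id,
                     c("participant_id", "age_group")]

  grp <- dplyr::left_join(
    sel[, c("participant_id", "food_code")],
    catalogue[, c("food_code", "food_group")],
    by = "food_code"
  )
  grp <- dplyr::left_join(grp, pp, by = "participant_id")
  core <- grp[as.character(grp$food_group) %in% dds_food_groups(), ]
  core$food_group <- factor(as.character(core$food_group),
                            levels = dds_food_groups())

  # distinct items per participant x group, with explicit zeros
  indiv <- dplyr::summarise(
    dplyr::group_by(core, .data$participant_id, .data$food_group,
                    .drop = FALSE),
    individual_items = dplyr::n_distinct(.data$food_code), .groups = "drop")
  indiv <- tidyr::complete(
    indiv,
    participant_id = pp$participant_id,
    food_group = factor(dds_food_groups(), levels = dds_food_groups()),
    fill = list(individual_items = 0L))
  indiv <- dplyr::left_join(indiv, pp, by = "participant_id")

  # age-group-wide distinct totals per group
  totals <- dplyr::summarise(
    dplyr::group_by(core_with_age(core, pp), .data$age_group,
                    .data$food_group, .drop = FALSE),
    total_study_items = dplyr::n_distinct(.data$food_code),
    .groups = "drop")
  indiv <- dplyr::left_join(indiv, totals, by = c("age_group", "food_group"))
  if (any(indiv$total_study_items < 1)) {
    bad <- unique(indiv[indiv$total_study_items < 1,
                        c("age_group", "food_group")])
    stop_validation(sprintf(
      "no food of group consumed in stratum: %s",
      paste(bad$age_group, bad$food_group, sep = "/", collapse = ", ")))
  }
  indiv$ratio <- compute_group_ratio(indiv$individual_items,
                                     indiv$total_study_items)

  # age-specific quartile points per group
  indiv <- dplyr::group_by(indiv, .data$age_group, .data$food_group)
  indiv <- dplyr::mutate(
    indiv, fg_dds_score = 1.5 * quantile_bin(.data$ratio, c(.25, .5, .75)))
  indiv <- dplyr::ungroup(indiv)

  wide <- tidyr::pivot_wider(
    indiv[, c("participant_id", "age_group", "food_group", "ratio",
              "fg_dds_score")],
    names_from = "food_group",
    values_from = c("ratio", "fg_dds_score"),
    names_glue = "{.value}_{food_group}")
  score_cols <- paste0("fg_dds_score_", dds_food_groups())
  wide$dds <- rowSums(as.matrix(wide[, score_cols]))

  # FVS over all rows (excluded-group foods count)
  fvs <- dplyr::summarise(
    dplyr::group_by(sel, .data$participant_id),
    individual_items_all = dplyr::n_distinct(.data$food_code),
    total_individual_items = dplyr::n(), .groups = "drop")
  fvs$fvs <- fvs$individual_items_all / fvs$total_individual_items
  out <- dplyr::left_join(wide, fvs, by = "participant_id")

  strata <- if (tertiles_by_age_group) as.character(out$age_group) else
    rep("all", nrow(out))
  out$dds_tertile <- stratified_tertiles(out$dds, strata)
  out$fvs_tertile <- stratified_tertiles(out$fvs, strata)
  attr(out, "exclusions") <- exclusions
  out
}

core_with_age <- function(core, pp) {
  if (!"age_group" %in% names(core)) {
    core <- dplyr::left_join(core, pp, by = "participant_id")
  }
  core$age_group <- factor(as.character(core$age_group),
                           levels = age_group_levels())
  core
}

stratified_tertiles <- function(values, strata) {
  out <- factor(rep(NA_character_, length(values)),
                levels = tertile_levels())
  for (s in unique(strata)) {
    ix <- strata == s
    out[ix] <- assign_tertiles(values[ix])
  }
  out
}
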