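# Delimited-text IO for the three tables. One canonical dialect: UTF-8,
# comma-delimited, header row, decimal point.

read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and write the food catalogue
#'
#' The catalogue CSV carries one row per food code with columns
#' `food_code, name, food_group, nova_class, energy_kcal, protein_g, fat_g,
#' sfa_g, carbohydrate_g, sugar_g, fiber_g, is_solid`; composition is per
#' 100 g. Reading validates the table (see [validate_catalogue()]).
#'
#' @param path Path to a CSV file.
#' @return `read_food_catalogue()` returns a validated catalogue tibble;
#'   `write_food_catalogue()` returns `path` invisibly.
#' @export
read_food_catalogue <- function(path) {
  validate_catalogue(read_table_csv(path))
}

#' @rdname read_food_catalogue
#' @param catalogue A validated catalogue.
#' @export
write_food_catalogue <- function(catalogue, path) {
  out <- as.data.frame(catalogue)
  out$food_group <- as.character(out$food_group)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write recall records
#'
#' Recall CSVs are long format: one row per (participant, recall day, food,
#' amount in grams, meal occasion). All food codes must resolve in the
#' catalogue; in lenient mode unresolved rows are dropped with a message.
#'
#' @param path Path to a CSV file.
#' @param catalogue Validated catalogue used to resolve food codes.
#' @param unknown_codes `"strict"` (default) or `"lenient"`.
#' @return A validated recall tibble.
#' @export
read_recalls <- function(path, catalogue,
                         unknown_codes = c("strict", "lenient")) {
  validate_recalls(read_table_csv(path), catalogue, unknown_codes)
}

#' @rdname read_recalls
#' @param recalls A validated recall table.
#' @export
write_recalls <- function(recalls, path) {
  readr::write_csv(as.data.frame(recalls), path, progress = FALSE)
  invisible(path)
}

#' Read and write the participant table
#'
#' @param path Path to a CSV file.
#' @return A validated participant tibble.
#' @export
read_participants <- function(path) {
  validate_participants(read_table_csv(path))
}

#' @rdname read_participants
#' @param participants A validated participant table.
#' @export
write_participants <- function(participants, path) {
  out <- as.data.frame(participants)
  for (col in c("sex", "age_group", "country", "isced")) {
    out[[col]] <- as.character(out[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Select each participant's analysis recalls
#'
#' Participants need at least `min_days` recall days to enter the analysis;
#' all scoring then uses exactly the first `min_days` days (the lowest recall
#' indices in chronological order). Participants with fewer days are removed
#' and reported in the exclusion attribute.
#'
#' @param recalls Validated recall table.
#' @param min_days Minimum (and retained) number of recall days; default 3.
#' @return Recall tibble restricted to `recall_index <= min_days` for
#'   participants with at least `min_days` days. The excluded participants
#'   are attached as attribute `"exclusions"` (a tibble of participant_id and
#'   reason), so the pipeline can write an exclusion report.
#' @export
select_analysis_recalls <- function(recalls, min_days = 3) {
  stopifnot(min_days >= 1)
  n_days <- tapply(recalls$recall_index, recalls$participant_id,
                   function(ix) length(unique(ix)))
  keep_ids <- names(n_days)[n_days >= min_days]
  dropped <- setdiff(names(n_days), keep_ids)
  out <- recalls[recalls$participant_id %in% keep_ids &
                   recalls$recall_index <= min_days, , drop = FALSE]
  if (length(dropped) > 0) {
    inform(sprintf("excluding %d participant(s) with < %d recall days",
                   length(dropped), min_days))
  }
  attr(out, "exclusions") <- tibble::tibble(
    participant_id = dropped,
    reason = sprintf("fewer than %d recall days", min_days)
  )
  out
}
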