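# Small fixtures built in code. tiny_catalogue() gives hand-written foods
# with round-number composition so expectations are arithmetic; small_config()
# keeps simulated cohorts quick.

tiny_catalogue <- function() {
  validate_catalogue(tibble::tibble(
    food_code = c("C1", "C2", "D1", "F1", "F2", "V1", "V2", "P1", "X1"),
    name = c("bread", "oats", "milk", "apple", "banana", "carrot", "pea",
             "chicken", "candy"),
    food_group = c("cereal", "cereal", "dairy", "fruit", "fruit",
                   "vegetables", "vegetables", "protein_foods", "excluded"),
    nova_class = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 3L, 4L),
    energy_kcal = c(250, 380, 64, 52, 89, 41, 81, 165, 400),
    protein_g = c(9, 13, 3.4, 0.3, 1.1, 0.9, 5.4, 31, 2),
    fat_g = c(3, 7, 3.6, 0.2, 0.3, 0.2, 0.4, 3.6, 15),
    sfa_g = c(0.6, 1.2, 2.3, 0.05, 0.1, 0.05, 0.1, 1, 9),
    carbohydrate_g = c(49, 68, 4.8, 14, 23, 10, 14, 0, 60),
    sugar_g = c(5, 1, 4.8, 10, 12, 4.7, 6, 0, 45),
    fiber_g = c(2.7, 10, 0, 2.4, 2.6, 2.8, 5, 0, 0.5),
    is_solid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  ))
}

recall_rows <- function(participant_id, day, codes, amount = 100) {
  tibble::tibble(
    participant_id = participant_id,
    recall_index = day,
    recall_date = as.Date("2014-03-03") + 4L * (day - 1L),
    food_code = codes,
    amount_g = amount,
    meal_occasion = "lunch"
  )
}

small_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed,
                   n_per_age_group = c(child = 40, teen = 40, adult = 60))
  do.call(sim_config, utils::modifyList(defaults, args))
}

adult_config <- function(seed, n = 500, ...) {
  sim_config(seed = seed,
             n_per_age_group = c(child = 0, teen = 0, adult = n), ...)
}

# small cohorts make sparse country/ISCED strata, so glm legitimately warns
# about fitted probabilities near 0/1; keep smoke tests quiet
quiet_pipeline <- function(...) {
  suppressWarnings(suppressMessages(run_pipeline(...)))
}

bundle_hashes <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  setNames(unname(tools::md5sum(files)), basename(files))
}
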