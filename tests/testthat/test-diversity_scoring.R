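# Worked example used across several tests: one participant whose per-group
# distinct-food counts match the published DDS calculation example
# (cereal 5, dairy 2, fruit 1, protein foods 5, vegetables 2).
example_counts <- c(cereal = 5L, dairy = 2L, fruit = 1L,
                    protein_foods = 5L, vegetables = 2L)

example_recalls <- function(cat) {
  codes_by_group <- split(cat$food_code, as.character(cat$food_group))
  rows <- lapply(names(example_counts), function(g) {
    recall_rows("ex1", 1, codes_by_group[[g]][seq_len(example_counts[[g]])])
  })
  validate_recalls(dplyr::bind_rows(rows), cat)
}

big_catalogue <- function() {
  generate_catalogue(small_config(
    seed = 2, catalogue_sizes = c(cereal = 8, dairy = 6, fruit = 6,
                                  vegetables = 6, protein_foods = 8,
                                  excluded = 4)))
}

test_that("distinct-item counting ignores repeats and amounts", {
  cat <- tiny_catalogue()
  rec <- validate_recalls(dplyr::bind_rows(
    recall_rows("p1", 1, "F1", amount = 50),
    recall_rows("p1", 2, "F1", amount = 300),
    recall_rows("p1", 3, c("F2", "C1"))
  ), cat)
  expect_equal(count_individual_items(rec, cat, "p1", "fruit"), 2)
  expect_equal(count_individual_items(rec, cat, "p1", "vegetables"), 0)
  expect_error(count_individual_items(rec, cat, "ghost", "fruit"),
               "ghost", class = "dietdiv_validation_error")
})

test_that("the worked-example participant has the published item counts", {
  cat <- big_catalogue()
  rec <- example_recalls(cat)
  for (g in names(example_counts)) {
    expect_equal(count_individual_items(rec, cat, "ex1", g),
                 unname(example_counts[[g]]))
  }
})

test_that("age-group study totals are the union of distinct codes", {
  cat <- tiny_catalogue()
  pp <- tibble::tibble(participant_id = c("a", "b"),
                       age_group = c("adult", "adult"))
  rec <- validate_recalls(dplyr::bind_rows(
    recall_rows("a", 1, c("C1", "C2")),
    recall_rows("b", 1, c("C2", "C1"))
  ), cat)
  expect_equal(compute_total_study_items(rec, cat, pp, "adult", "cereal"), 2)

  # single-participant cohort: total equals that participant's count
  rec_a <- rec[rec$participant_id == "a", ]
  expect_equal(compute_total_study_items(rec_a, cat, pp[1, ], "adult",
                                         "cereal"),
               count_individual_items(rec_a, cat, "a", "cereal"))
  expect_error(compute_total_study_items(rec, cat, pp, "child", "cereal"),
               class = "dietdiv_validation_error")
})

test_that("study totals match a brute-force set union on a simulated cohort", {
  cohort <- simulate_cohort(small_config(seed = 13))
  sel <- select_analysis_recalls(cohort$recalls)
  for (g in c("fruit", "cereal")) {
    codes_g <- cohort$catalogue$food_code[
      as.character(cohort$catalogue$food_group) == g]
    for (ag in age_group_levels()) {
      ids <- cohort$participants$participant_id[
        cohort$participants$age_group == ag]
      brute <- length(Reduce(union, lapply(ids, function(id) {
        intersect(sel$food_code[sel$participant_id == id], codes_g)
      })))
      expect_equal(compute_total_study_items(sel, cohort$catalogue,
                                             cohort$participants, ag, g),
                   brute)
    }
  }
})

test_that("group ratios are exact quotients with guarded domains", {
  expect_equal(compute_group_ratio(2, 100), 0.02)
  expect_equal(compute_group_ratio(0, 50), 0)
  expect_equal(round(compute_group_ratio(5, 220), 4), 0.0227)
  expect_error(compute_group_ratio(1, 0), class = "dietdiv_validation_error")
  expect_error(compute_group_ratio(6, 5), class = "dietdiv_validation_error")
})

test_that("quartile scores follow the 1.5/3/4.5/6 ladder with right-closed ties", {
  sc <- assign_fg_scores(c(a = 0.1, b = 0.2, c = 0.3, d = 0.4))
  expect_equal(sc$fg_dds_score[match(c("a", "b", "c", "d"),
                                     sc$participant_id)],
               c(1.5, 3, 4.5, 6))
  expect_equal(sc$fg_dds_score, 1.5 * sc$quartile)

  tied <- assign_fg_scores(setNames(rep(0.2, 6), paste0("p", 1:6)))
  expect_true(all(tied$fg_dds_score == 1.5))

  expect_error(assign_fg_scores(c(a = 0.1, b = 0.2, c = 0.3)),
               class = "dietdiv_validation_error")
})

test_that("quantile binning matches a rank-based oracle on untied values", {
  set.seed(99)
  x <- runif(1000)
  bins <- quantile_bin(x, c(.25, .5, .75))
  cuts <- quantile(x, c(.25, .5, .75), type = 7)
  oracle <- 1L + findInterval(x, cuts, left.open = TRUE)
  expect_equal(bins, oracle)
  # scale invariance: positive rescaling leaves quartile bins unchanged
  expect_equal(quantile_bin(37.5 * x, c(.25, .5, .75)), bins)
})

test_that("DDS is the sum of five group scores with the printed extremes", {
  expect_equal(compute_dds(c(4.5, 3.0, 3.0, 4.5, 1.5)), 16.5)
  expect_equal(compute_dds(rep(6, 5)), 30)
  expect_equal(compute_dds(rep(1.5, 5)), 7.5)
  expect_error(compute_dds(c(4.5, 3, 3, 4.5, NA)),
               class = "dietdiv_validation_error")
  expect_error(compute_dds(c(4.5, 3, 3, 4.5)),
               class = "dietdiv_validation_error")
  expect_error(compute_dds(c(4.5, 3, 3, 4.5, 2)),
               class = "dietdiv_validation_error")
})

test_that("FVS is distinct over total foods, duplicates counted per row", {
  cat <- tiny_catalogue()
  # 17 consumption rows spanning 15 distinct codes -> 0.88 at 2 decimals
  codes17 <- c(paste0("S", 1:15), "S1", "S2")
  cat15 <- validate_catalogue(tibble::tibble(
    food_code = paste0("S", 1:15), name = paste0("food", 1:15),
    food_group = rep(c("cereal", "dairy", "fruit", "vegetables",
                       "protein_foods"), 3),
    nova_class = 1L, energy_kcal = 100, protein_g = 5, fat_g = 2,
    sfa_g = 1, carbohydrate_g = 15, sugar_g = 5, fiber_g = 1,
    is_solid = TRUE))
  rec <- validate_recalls(dplyr::bind_rows(
    recall_rows("t2", 1, codes17[1:6]), recall_rows("t2", 2, codes17[7:12]),
    recall_rows("t2", 3, codes17[13:17])), cat15)
  out <- compute_fvs(rec, "t2")
  expect_equal(out$individual_items, 15)
  expect_equal(out$total_individual_items, 17)
  expect_equal(round(out$fvs, 2), 0.88)

  rec1 <- validate_recalls(recall_rows("p", 1, c("C1", "F1", "V1")), cat)
  expect_equal(compute_fvs(rec1, "p")$fvs, 1)
  rec10 <- validate_recalls(recall_rows("p", 1, rep("C1", 10)), cat)
  expect_equal(compute_fvs(rec10, "p")$fvs, 0.1)
  expect_error(compute_fvs(rec1, "nobody"),
               class = "dietdiv_validation_error")
})

test_that("tertile assignment splits at the 33/67 percentiles", {
  t1 <- assign_tertiles(setNames(1:9, paste0("p", 1:9)))
  expect_equal(as.vector(table(t1)), c(3, 3, 3))
  t2 <- assign_tertiles(setNames(rep(1:3, each = 3), paste0("p", 1:9)))
  expect_equal(as.character(t2), rep(c("low", "medium", "high"), each = 3))
  expect_warning(t3 <- assign_tertiles(c(a = 2, b = 2, c = 2)), "identical")
  expect_true(all(t3 == "low"))

  # tie accounting on a coarse score scale
  set.seed(3)
  dds_like <- sample(seq(7.5, 30, by = 1.5), 500, replace = TRUE)
  tert <- assign_tertiles(dds_like)
  cuts <- quantile(dds_like, c(1 / 3, 2 / 3), type = 7)
  tol <- sum(dds_like %in% (round(cuts / 1.5) * 1.5))
  expect_true(all(abs(table(tert) - 500 / 3) <= tol))
})

test_that("cohort scoring conserves sums, ranges and monotonicity", {
  cohort <- simulate_cohort(small_config(seed = 17))
  sc <- score_diversity(cohort$recalls, cohort$catalogue,
                        cohort$participants)
  score_cols <- paste0("fg_dds_score_", dds_food_groups())
  expect_equal(sc$dds, rowSums(as.matrix(sc[, score_cols])))
  expect_true(all(sc$dds >= 7.5 & sc$dds <= 30))
  expect_true(all(abs(sc$dds / 1.5 - round(sc$dds / 1.5)) < 1e-9))
  expect_true(all(sc$fvs > 0 & sc$fvs <= 1))

  # distinct-item counts match a naive set recount
  sel <- select_analysis_recalls(cohort$recalls)
  ids <- sample(sc$participant_id, 5)
  for (id in ids) {
    for (g in dds_food_groups()) {
      codes_g <- cohort$catalogue$food_code[
        as.character(cohort$catalogue$food_group) == g]
      naive <- length(unique(intersect(
        sel$food_code[sel$participant_id == id], codes_g)))
      ratio <- sc[[paste0("ratio_", g)]][sc$participant_id == id]
      total <- compute_total_study_items(
        sel, cohort$catalogue, cohort$participants,
        as.character(sc$age_group[sc$participant_id == id]), g)
      expect_equal(ratio * total, naive, tolerance = 1e-9)
    }
  }
})

test_that("adding a distinct food never decreases the group ratio or DDS", {
  cohort <- simulate_cohort(small_config(seed = 19))
  sc1 <- score_diversity(cohort$recalls, cohort$catalogue,
                         cohort$participants)
  # give one participant a fruit food they have not eaten
  fruit_codes <- cohort$catalogue$food_code[
    as.character(cohort$catalogue$food_group) == "fruit"]
  sel <- select_analysis_recalls(cohort$recalls)
  id <- sc1$participant_id[which.min(sc1$ratio_fruit)]
  new_code <- setdiff(fruit_codes, sel$food_code[sel$participant_id == id])[1]
  extra <- recall_rows(id, 1, new_code)
  extra$recall_date <- sel$recall_date[sel$recall_index == 1][1]
  rec2 <- dplyr::bind_rows(as.data.frame(cohort$recalls), extra)
  sc2 <- score_diversity(validate_recalls(rec2, cohort$catalogue),
                         cohort$catalogue, cohort$participants)
  i1 <- match(id, sc1$participant_id)
  i2 <- match(id, sc2$participant_id)
  expect_gte(sc2$ratio_fruit[i2], sc1$ratio_fruit[i1])
  expect_gte(sc2$dds[i2], sc1$dds[i1])
})

test_that("total items rise across DDS tertiles and fall across FVS tertiles", {
  cohort <- simulate_cohort(sim_config(
    seed = 23, n_per_age_group = c(child = 0, teen = 0, adult = 600)))
  sc <- score_diversity(cohort$recalls, cohort$catalogue,
                        cohort$participants)
  by_dds <- tapply(sc$individual_items_all, sc$dds_tertile, mean)
  by_fvs <- tapply(sc$individual_items_all, sc$fvs_tertile, mean)
  expect_true(all(diff(by_dds[tertile_levels()]) > 0))
  expect_true(all(diff(by_fvs[tertile_levels()]) < 0))
})
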