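make_tertile_data <- function(n_per = 40, effect = 0, sd = 1, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    tert = factor(rep(tertile_levels(), each = n_per),
                  levels = tertile_levels()),
    y = effect * rep(0:2, each = n_per) + rnorm(3 * n_per, sd = sd)
  )
}

test_that("a single constant tertile gives its mean with a zero-width CI", {
  df <- tibble::tibble(tert = factor(rep("low", 5), levels = "low"), y = 3)
  mm <- tertile_marginal_means(df, "y", "tert")
  expect_equal(mm$means$mean, 3)
  expect_equal(mm$means$ci_high - mm$means$ci_low, 0)
})

test_that("unadjusted marginal means equal arithmetic group means", {
  df <- make_tertile_data(n_per = 25, effect = 0.7, seed = 2)
  mm <- tertile_marginal_means(df, "y", "tert")
  direct <- tapply(df$y, df$tert, mean)
  expect_equal(mm$means$mean, as.numeric(direct[mm$means$tertile]),
               tolerance = 1e-9)
})

test_that("marginal means recover an injected tertile gradient", {
  df <- make_tertile_data(n_per = 100, effect = 1, seed = 3)
  mm <- tertile_marginal_means(df, "y", "tert")$means
  diffs <- diff(mm$mean[match(tertile_levels(), mm$tertile)])
  expect_true(all(abs(diffs - 1) < 0.3))
})

test_that("collinear covariates are reported by name", {
  df <- make_tertile_data(n_per = 20, seed = 4)
  df$x1 <- rnorm(nrow(df))
  df$x2 <- 2 * df$x1
  expect_error(tertile_marginal_means(df, "y", "tert", c("x1", "x2")),
               "x2", class = "dietdiv_validation_error")
})

test_that("pairwise flags match a 3-fold Bonferroni on unadjusted p-values", {
  df <- make_tertile_data(n_per = 60, effect = 0.25, seed = 5)
  mm <- tertile_marginal_means(df, "y", "tert")
  flags <- pairwise_bonferroni(mm$emm, alpha = 0.05)
  raw <- summary(emmeans::contrast(mm$emm, "pairwise", adjust = "none"))
  oracle_sig <- setNames(pmin(1, 3 * raw$p.value) < 0.05,
                         as.character(raw$contrast))
  expect_equal(unname(flags$sig_vs_medium[flags$tertile == "low"]),
               unname(oracle_sig[["low - medium"]]))
  expect_equal(unname(flags$sig_vs_high[flags$tertile == "low"]),
               unname(oracle_sig[["low - high"]]))
  expect_equal(unname(flags$sig_vs_high[flags$tertile == "medium"]),
               unname(oracle_sig[["medium - high"]]))
  # symmetry of the flag matrix
  expect_equal(flags$sig_vs_low[flags$tertile == "high"],
               flags$sig_vs_high[flags$tertile == "low"])
  # monotone in alpha: significant at 0.01 implies significant at 0.05
  strict <- pairwise_bonferroni(mm$emm, alpha = 0.01)
  lax <- pairwise_bonferroni(mm$emm, alpha = 0.05)
  s <- attr(strict, "contrasts")$p_adjusted < 0.01
  l <- attr(lax, "contrasts")$p_adjusted < 0.05
  expect_true(all(!s | l))
})

test_that("an injected 2-SD low-vs-high difference is flagged with power", {
  hits <- vapply(1:40, function(r) {
    df <- make_tertile_data(n_per = 100, effect = 1, sd = 1, seed = 100 + r)
    mm <- tertile_marginal_means(df, "y", "tert")
    flags <- pairwise_bonferroni(mm$emm)
    isTRUE(flags$sig_vs_high[flags$tertile == "low"])
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

logistic_sim <- function(n, log_or_high, seed) {
  set.seed(seed)
  tert <- factor(sample(tertile_levels(), n, replace = TRUE),
                 levels = tertile_levels())
  lp <- -0.3 + log_or_high * (tert == "high") +
    (log_or_high / 2) * (tert == "medium")
  tibble::tibble(
    bmi_category = ifelse(rbinom(n, 1, plogis(lp)) == 1, "overweight",
                          "normal"),
    tert = tert,
    sex = sample(c("female", "male"), n, replace = TRUE),
    age_years = runif(n, 20, 70),
    country = sample(country_levels(), n, replace = TRUE),
    isced = sample(isced_levels(), n, replace = TRUE),
    energy_kcal_day = rnorm(n, 2000, 300)
  )
}

test_that("the 2x2 closed-form odds ratio is recovered exactly", {
  df <- tibble::tibble(
    bmi_category = rep(c("overweight", "normal", "overweight", "normal"),
                       c(40, 10, 20, 30)),
    tert = rep(c("low", "low", "high", "high"), c(40, 10, 20, 30)),
    sex = "female", age_years = 30, country = "Italy", isced = "high",
    energy_kcal_day = 2000
  )
  res <- fit_overweight_logistic(df, "tert", model = "a")
  expect_equal(nrow(res), 1)
  # odds ratio of high vs low: (20/30) / (40/10)
  expect_equal(res$odds_ratio, (20 * 10) / (30 * 40), tolerance = 1e-6)
  res_b <- fit_overweight_logistic(df, "tert", model = "b")
  expect_equal(res$odds_ratio, res_b$odds_ratio, tolerance = 1e-6)
})

test_that("null logistic CIs cover 1 and injected effects are recovered", {
  covered <- vapply(1:40, function(r) {
    res <- fit_overweight_logistic(logistic_sim(800, 0, seed = 200 + r),
                                   "tert", model = "a")
    all(res$ci_low <= 1 & res$ci_high >= 1)
  }, logical(1))
  expect_gte(mean(covered), 0.9)

  ors <- vapply(1:60, function(r) {
    res <- fit_overweight_logistic(logistic_sim(2000, -0.5, seed = 300 + r),
                                   "tert", model = "a")
    res$odds_ratio[res$contrast == "high vs low"]
  }, numeric(1))
  expect_lt(abs(mean(ors) - exp(-0.5)), 0.1)
})

test_that("logistic CIs always contain their odds ratio", {
  res <- fit_overweight_logistic(logistic_sim(500, -0.4, seed = 7), "tert",
                                 model = "b")
  expect_true(all(res$ci_low <= res$odds_ratio &
                    res$odds_ratio <= res$ci_high))
  expect_true(all(res$odds_ratio > 0))
})
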