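# Tertile association analysis: (adjusted) marginal means with 95% CIs and
# Bonferroni-corrected pairwise contrasts per outcome, and logistic
# regression of overweight/obesity on score tertiles with covariate
# adjustment. Marginal means and contrasts are computed with the emmeans
# package over a linear model fit.

#' Marginal means of an outcome across tertiles
#'
#' Fits a general linear model of the outcome on the tertile factor plus any
#' adjustment covariates and evaluates marginal means with 95% confidence
#' intervals on the covariate-balanced reference grid (categorical covariates
#' weighted equally; switch to `weights = "proportional"` for
#' observed-proportion weighting). With an empty covariate set this reduces
#' to plain per-tertile means.
#'
#' @param data Data frame holding the outcome, the tertile column and the
#'   covariates.
#' @param outcome Name of the (numeric) outcome column.
#' @param tertile_col Name of the tertile factor column.
#' @param covariates Character vector of adjustment covariate names (default
#'   none: unadjusted means).
#' @param weights Reference-grid weighting passed to [emmeans::emmeans()].
#' @return List with `means` (tibble: tertile, mean, ci_low, ci_high, n) and
#'   `emm` (the emmeans object, for contrast computation).
#' @export
tertile_marginal_means <- function(data, outcome, tertile_col,
                                   covariates = character(),
                                   weights = c("equal", "proportional")) {
  weights <- match.arg(weights)
  df <- data[, c(outcome, tertile_col, covariates), drop = FALSE]
  levels_in <- unique(as.character(df[[tertile_col]][
    !is.na(df[[tertile_col]])]))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0) {
    stop_validation(sprintf("no complete observations for outcome '%s'",
                            outcome))
  }
  df[[tertile_col]] <- droplevels(factor(df[[tertile_col]],
                                         levels = tertile_levels()))
  counts <- table(df[[tertile_col]])
  if (length(setdiff(levels_in, names(counts))) > 0 || any(counts < 2)) {
    stop_validation(sprintf(
      "tertile with fewer than 2 complete observations for outcome '%s'",
      outcome))
  }
  if (nlevels(df[[tertile_col]]) == 1) {
    # degenerate single-tertile input: plain mean with a t interval
    v <- df[[outcome]]
    se <- stats::sd(v) / sqrt(length(v))
    hw <- stats::qt(0.975, length(v) - 1) * se
    return(list(means = tibble::tibble(
      tertile = levels(df[[tertile_col]]), mean = mean(v),
      ci_low = mean(v) - hw, ci_high = mean(v) + hw, n = length(v)),
      emm = NULL, n_used = nrow(df)))
  }
  fit <- lm(reformulate(c(tertile_col, covariates), response = outcome),
            data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_validation(sprintf("collinear model terms: %s",
                            paste(bad, collapse = ", ")))
  }
  emm <- emmeans::emmeans(fit, specs = tertile_col, weights = weights)
  s <- summary(emm, level = 0.95)
  means <- tibble::tibble(
    tertile = as.character(s[[tertile_col]]),
    mean = s$emmean,
    ci_low = s$lower.CL,
    ci_high = s$upper.CL,
    n = as.integer(counts[as.character(s[[tertile_col]])])
  )
  list(means = means, emm = emm, n_used = nrow(df))
}

#' Bonferroni-corrected pairwise tertile contrasts
#'
#' Tests the three pairwise contrasts between tertile marginal means with a
#' Bonferroni correction over the family of three comparisons (per outcome
#' and per diversity index), flagging significance at `alpha`.
#'
#' @param emm An emmeans object from [tertile_marginal_means()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return Tibble with one row per tertile: logical `sig_vs_low`,
#'   `sig_vs_medium`, `sig_vs_high` (NA against itself), mirroring the
#'   m/h superscript convention; plus attribute `"contrasts"` with the raw
#'   contrast table (estimate, Bonferroni-adjusted p).
#' @export
pairwise_bonferroni <- function(emm, alpha = 0.05) {
  if (is.null(emm)) {
    return(tibble::tibble(tertile = character(), sig_vs_low = logical(),
                          sig_vs_medium = logical(),
                          sig_vs_high = logical()))
  }
  ct <- summary(emmeans::contrast(emm, method = "pairwise",
                                  adjust = "bonferroni"))
  parts <- strsplit(as.character(ct$contrast), " - ", fixed = TRUE)
  a <- vapply(parts, `[[`, character(1), 1)
  b <- vapply(parts, `[[`, character(1), 2)
  sig <- ct$p.value < alpha
  levs <- intersect(tertile_levels(), union(a, b))
  flags <- matrix(NA, nrow = length(levs), ncol = length(levs),
                  dimnames = list(levs, levs))
  for (k in seq_along(a)) {
    flags[a[k], b[k]] <- sig[k]
    flags[b[k], a[k]] <- sig[k]
  }
  col <- function(lv) if (lv %in% levs) unname(flags[, lv]) else NA
  out <- tibble::tibble(
    tertile = levs,
    sig_vs_low = col("low"),
    sig_vs_medium = col("medium"),
    sig_vs_high = col("high")
  )
  attr(out, "contrasts") <- tibble::tibble(
    contrast = as.character(ct$contrast), estimate = ct$estimate,
    p_adjusted = ct$p.value)
  out
}

#' Logistic regression of overweight/obesity on score tertiles
#'
#' Binary outcome: overweight or obese versus normal weight. The low tertile
#' is the reference; model "a" adjusts for sex, age, country and ISCED,
#' model "b" additionally for total daily energy intake. Odds ratios are
#' exponentiated coefficients with Wald 95% confidence intervals.
#'
#' @param data Data frame with columns `bmi_category`, the tertile column,
#'   `sex`, `age_years`, `country`, `isced` and (for model b)
#'   `energy_kcal_day`.
#' @param tertile_col Name of the tertile factor column.
#' @param model `"a"` (sex, age, country, ISCED) or `"b"` (+ energy).
#' @return Tibble with one row per non-reference tertile: `contrast`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `model`, `n_used`.
#' @export
fit_overweight_logistic <- function(data, tertile_col, model = c("a", "b")) {
  model <- match.arg(model)
  covars <- c("sex", "age_years", "country", "isced")
  if (model == "b") covars <- c(covars, "energy_kcal_day")
  df <- data[, c("bmi_category", tertile_col, covars), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$ow_ob <- as.integer(df$bmi_category %in% c("overweight", "obese"))
  df[[tertile_col]] <- droplevels(factor(as.character(df[[tertile_col]]),
                                         levels = tertile_levels()))
  if (nlevels(df[[tertile_col]]) < 2 ||
      !"low" %in% levels(df[[tertile_col]])) {
    stop_validation("need the low reference tertile plus at least one other")
  }
  for (cv in intersect(c("sex", "country", "isced"), covars)) {
    f <- droplevels(factor(df[[cv]]))
    if (nlevels(f) < nlevels(factor(df[[cv]], levels = levels(df[[cv]])))) {
      warn(sprintf("dropping empty level(s) of '%s'", cv))
    }
    if (nlevels(f) < 2) covars <- setdiff(covars, cv) else df[[cv]] <- f
  }
  # constant numeric covariates carry no information and break the fit
  for (cv in intersect(c("age_years", "energy_kcal_day"), covars)) {
    if (stats::var(df[[cv]]) == 0) covars <- setdiff(covars, cv)
  }
  fit <- glm(reformulate(c(tertile_col, covars), response = "ow_ob"),
             data = df, family = binomial())
  if (!fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE)) {
    stop_validation(paste(
      "logistic fit did not converge cleanly (possible complete",
      "separation); consider pooling sparse strata or dropping covariates"))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  keep <- grep(paste0("^", tertile_col), names(est), value = TRUE)
  lev <- sub(paste0("^", tertile_col), "", keep)
  pv <- 2 * stats::pnorm(-abs(est[keep] / se[keep]))
  tibble::tibble(
    contrast = paste(lev, "vs low"),
    odds_ratio = unname(exp(est[keep])),
    ci_low = unname(exp(est[keep] - z * se[keep])),
    ci_high = unname(exp(est[keep] + z * se[keep])),
    p_value = unname(as.numeric(pv)),
    model = model,
    n_used = nrow(df)
  )
}

#' Tertile association table for a set of outcomes
#'
#' Builds the per-age-group, per-index association surface: for every
#' outcome, tertile marginal means with 95% CIs and Bonferroni pairwise
#' significance flags.
#'
#' @param data Data frame with `age_group`, the tertile columns and the
#'   outcome columns.
#' @param outcomes Character vector of outcome column names.
#' @param tertile_col Tertile column (e.g. `"dds_tertile"`).
#' @param index Label for the diversity index ("DDS" or "FVS").
#' @param covariates Adjustment covariates (default none: unadjusted means).
#' @param alpha Family-wise level for the pairwise flags.
#' @return Long tibble: age_group, index, outcome, tertile, mean, ci_low,
#'   ci_high, n, sig_vs_low/medium/high.
#' @export
association_table <- function(data, outcomes, tertile_col, index,
                              covariates = character(), alpha = 0.05) {
  rows <- list()
  for (ag in intersect(age_group_levels(),
                       unique(as.character(data$age_group)))) {
    sub <- data[as.character(data$age_group) == ag, , drop = FALSE]
    for (oc in outcomes) {
      mm <- tryCatch(
        tertile_marginal_means(sub, oc, tertile_col, covariates),
        dietdiv_validation_error = function(e) {
          inform(sprintf("skipping outcome '%s' in age group '%s': %s",
                         oc, ag, conditionMessage(e)))
          NULL
        })
      if (is.null(mm)) next
      flags <- pairwise_bonferroni(mm$emm, alpha)
      tab <- dplyr::left_join(mm$means, flags, by = "tertile")
      tab <- tibble::add_column(tab, age_group = ag, index = index,
                                outcome = oc, .before = 1)
      rows[[length(rows) + 1]] <- tab
    }
  }
  dplyr::bind_rows(rows)
}
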