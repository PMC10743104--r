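#' Right-closed quantile binning
#'
#' Assigns each value to a bin defined by empirical quantile cutpoints.
#' Cutpoints are computed with linear interpolation (`stats::quantile`
#' type 7). Bins are right-closed: a value equal to a cutpoint falls in the
#' lower bin, so tied values always share a bin and the all-equal degenerate
#' case maps everything to bin 1.
#'
#' @param x Numeric vector of values to bin.
#' @param probs Cutpoint probabilities, e.g. `c(.25, .5, .75)` for quartiles.
#' @param quantile_type Quantile estimator passed to [stats::quantile()].
#' @return Integer bin indices in `1:(length(probs) + 1)`.
#' @examples
#' quantile_bin(c(0.1, 0.2, 0.3, 0.4), c(.25, .5, .75))
#' @export
quantile_bin <- function(x, probs, quantile_type = 7) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  cuts <- stats::quantile(x, probs = probs, type = quantile_type,
                          names = FALSE)
  bins <- rep(1L, length(x))
  for (ct in cuts) bins <- bins + (x > ct)
  as.integer(bins)
}

# shared enum levels -----------------------------------------------------

#' Controlled vocabularies of the data model
#'
#' Factor levels used throughout the package: the five diversity food groups
#' (plus the `excluded` bucket of condiments, sauces and energy-dense
#' nutrient-poor items that never enters DDS group counting), age groups,
#' the eight study countries, ISCED strata and BMI categories.
#'
#' @return Character vector of levels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
food_group_levels <- function() {
  c("cereal", "dairy", "fruit", "vegetables", "protein_foods", "excluded")
}

#' @rdname vocabularies
#' @export
dds_food_groups <- function() {
  c("cereal", "dairy", "fruit", "protein_foods", "vegetables")
}

#' @rdname vocabularies
#' @export
age_group_levels <- function() c("child", "teen", "adult")

#' @rdname vocabularies
#' @export
country_levels <- function() {
  c("Belgium", "Cyprus", "Estonia", "Germany", "Hungary", "Italy",
    "Spain", "Sweden")
}

#' @rdname vocabularies
#' @export
isced_levels <- function() c("low", "medium", "high")

#' @rdname vocabularies
#' @export
bmi_category_levels <- function() c("normal", "overweight", "obese")

#' @rdname vocabularies
#' @export
tertile_levels <- function() c("low", "medium", "high")

#' Age group from age in years
#'
#' Children are 6 to <12 years, teens 12 to <20, adults 20 and over.
#'
#' @param age_years Numeric vector of ages.
#' @return Factor with levels child/teen/adult.
#' @export
age_group_of <- function(age_years) {
  stopifnot(all(age_years >= 6))
  cut(age_years, breaks = c(6, 12, 20, Inf), right = FALSE,
      labels = age_group_levels(), include.lowest = TRUE)
}

stop_schema <- function(msg) abort(msg, class = "dietdiv_schema_error")
stop_validation <- function(msg) abort(msg, class = "dietdiv_validation_error")
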