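---
title: "Dietary diversity scoring and tertile associations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary diversity scoring and tertile associations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietdiv)
```

## The scores

`dietdiv` computes two diet-variety indices from multi-day 24-hour dietary
recall data.

**Dietary diversity score (DDS).** Five food groups enter the score: cereals,
dairy products, fruits, vegetables, and protein-rich foods (legumes, meat,
fish, eggs). Condiments, sauces and energy-dense nutrient-poor foods
(alcohol, sugared drinks, snacks, cakes, sugar, confectionery) are kept in
the recall data — they still count toward energy, ultra-processed energy
share and the FVS — but are excluded from DDS group counting. For each age
group (6–<12, 12–<20, ≥20 years) and each food group, the number of distinct
food codes consumed by anyone in the age group over the three analysis days
defines the group's *total study items*. Each participant's distinct-food
count in the group divided by that total is their group ratio. Age-specific
quartiles of the ratios award 1.5 / 3 / 4.5 / 6 points, and the five group
scores sum to the DDS, so the score runs from 7.5 to 30 in steps of 1.5.

**Food variety score (FVS).** The number of distinct foods divided by the
total number of foods (every consumption row counts, with multiplicity) a
participant reported over the first three recall days; it lies in (0, 1].

Participants need at least three recall days to be scored; exactly the first
three days (lowest recall indices in chronological order) enter every
computation, so DDS, FVS and all intake metrics describe the same
observation window. Exclusions are reported, never silent.

### Numerical choices

* **Quantile rule.** Quartile, tertile and quintile cutpoints use empirical
  percentiles with linear interpolation (`stats::quantile`, type 7), the
  common default. No estimator is canonical for these scores; the choice is
  centralised in `quantile_bin()` and documented here so it can be revisited
  in one place.
* **Ties.** Bins are right-closed: a value equal to a cutpoint falls in the
  lower bin, tied values always share a bin, and the degenerate all-equal
  case maps everyone to the bottom bin (tertile assignment warns when this
  happens). This matters in practice: group ratios live on a coarse grid of
  integer counts over a shared denominator, so ties at cutpoints are common
  and an open/closed convention changes individual scores. A consequence
  worth knowing: with heavy ties the mean DDS sits below the 18.75 points
  that equal-sized quartile bins would give, because tied blocks are pushed
  into lower bins together.
* **Zero consumption.** A participant who ate nothing in a group enters the
  quartile computation with ratio 0 — it is a real observation, not missing
  data — and therefore still receives a group score.
* **Stratification.** Group quartiles are age-specific. Tertiles of DDS and
  FVS are computed within age group by default (`tertiles_by_age_group =
  FALSE` pools the cohort), since all reporting is age-stratified.
* **Cutpoint sample.** A participant's own ratio is included when computing
  the cutpoints that bin them (no leave-one-out), matching a one-pass cohort
  computation.
* **Food identity.** A food is its catalogue code; the same code on
  different days or occasions is one item for distinct counts.

## Diet-quality metrics

Daily nutrient totals are `amount_g x composition / 100 g` summed per day
and averaged over the three analysis days. Macronutrient energy shares use
Atwater factors (4/9/4 kcal per g of protein/fat/carbohydrate), with sugar
and saturated fat as sub-shares of carbohydrate and fat energy; on a
catalogue whose energies are Atwater-consistent the three shares close to
100% exactly. Dietary energy density divides mean daily energy from solid
foods by mean daily grams of solid foods — both numerator and denominator
are restricted to solids, reading "solid foods only" as qualifying the whole
quotient; whether beverage energy belonged in the numerator is genuinely
ambiguous, so the restriction is kept symmetric and beverages simply do not
enter. The ultra-processed food (UPF) share is the percent of total energy
from NOVA class 4 foods, split into quintiles within age group x sex. FFQ
propensities divide the weekly frequency of flagged (sugar-rich, fat-rich)
items by the total frequency of all items. HOMA-IR is glucose (mmol/L) x
insulin (mU/L) / 22.5. Adult BMI categories cut at 25 and 30 kg/m²; minors
carry categories derived from external reference tables as inputs.

## Association analysis

For each age group, diversity index and outcome, a general linear model of
the outcome on the tertile factor (plus any adjustment covariates) yields
marginal means and 95% CIs via the emmeans package. The default reference
grid weights categorical covariates equally (`weights = "proportional"`
switches to observed proportions); with no covariates the marginal means are
exactly the per-tertile sample means. The three pairwise contrasts are
tested with a Bonferroni correction per outcome and per index at a
family-wise 0.05; flags are stored symmetrically (low-vs-high significant
implies high-vs-low). Descriptive tables are unadjusted by default; passing
covariates (e.g. sex, age, country, ISCED, BMI) reproduces the adjusted
mode, since published tables of this kind appear in both forms.

Overweight/obesity (overweight or obese vs normal weight) is regressed on
the tertiles by maximum-likelihood logistic regression with the low tertile
as reference — model "a" adjusts for sex, age, country and parental-education
(ISCED) category; model "b" adds total daily energy intake. Odds ratios are
exponentiated coefficients with Wald 95% intervals (profile-likelihood
intervals would also be defensible; Wald matches common practice). Constant
or single-level covariates are dropped, empty factor levels are dropped with
a warning, and a fit that fails to converge or shows coefficient magnitudes
typical of complete separation aborts with guidance rather than returning
meaningless intervals. Participants missing any model variable are dropped
per analysis (complete cases), with the used n reported.

## The synthetic cohort generator

The study data this pipeline was designed for are access-restricted, so the
generator produces cohorts with the same three-table structure: a food
catalogue with group-typical nutrient profiles, participants across eight
countries, three age groups, both sexes and three parental-education strata,
and three recall days per participant. Defaults describe a cohort of 3035
participants (1012/1012/1011 per age group), 41% male and 64.8% high-ISCED.

Each participant carries a latent diversity propensity `d ~ Normal(0, 1)`
that is *not* observable downstream (it is written to a separate truth file)
and drives four injectable effects:

* `beta_fv` (default 2): expected distinct fruit+vegetable foods over the
  3 days rise by `beta_fv` per unit `d` (the other core groups move at a
  quarter of that slope).
* `beta_fiber` (default 3 g/day): injected through the daily amount of a
  high-fiber wholegrain staple every participant eats, so fiber shifts
  without touching distinct-food counts.
* `beta_upf` (default −5): NOVA-4 foods are down-weighted in food selection
  as `d` rises, lowering the UPF energy share without changing how many
  distinct foods are eaten.
* `beta_obesity` (default −0.5): the high-vs-low log-odds of adult
  overweight/obesity across thirds of `d` (the middle third sits halfway).
  Defining the effect on the thirds scale makes the injected quantity the
  same contrast the tertile logistic regression estimates, so recovery tests
  compare like with like; the recovered odds ratio is attenuated only by
  DDS-tertile misclassification of the latent thirds.
* `intake_volume_slope` (default 0.25): meal slots per day grow with `d`.
  Diverse eaters report more eating occasions and more energy; this is also
  what makes the variety ratio FVS *fall* as diversity rises (the
  distinct-food numerator grows more slowly than the total-food
  denominator), reproducing the opposite behaviour of the two indices.

With all betas and the volume slope at zero, diet is independent of `d` by
construction — the null configuration used for type-I-error checks. Effect
sizes were chosen once for test power: the source study reports tertile
contrasts, not per-unit effect sizes, so no empirical value exists to match.

**What the generator does not emulate:** national food-consumption
distributions, seasonality, day-of-week effects, correlated food choices
(menus), under-reporting, or realistic joint distributions of biomarkers
with adiposity (biomarkers other than BMI are generated independent of `d`).
Passing tests therefore demonstrate that the scoring and inference machinery
is correct and recovers known structure — not that any substantive finding
generalises to real dietary data.

## Problem sizes in the test suite

Worked-example and unit tests run on hand-built fixtures of a few rows.
Oracle-equivalence checks use a 1000-participant simulated cohort; effect
recovery uses adult cohorts of n = 2000 with 200 replicates for the odds
ratio; type-I error uses 500 null replicates of n = 150. These sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances
(e.g. a family-wise rate of 5% estimated over 500 replicates has SE ≈ 1
percentage point, against an asserted ceiling of 7%).

## Known limitations

* The fats food group is not part of the DDS (five groups only), and
  amount-weighted or entropy-based diversity indices are out of scope.
* FVS occurrence counting treats every recall row as one food; if an
  instrument splits one dish into several rows, FVS drops mechanically.
* Whether study tertiles should be computed within age group or cohort-wide
  is not determinable from the source description; within-age-group is the
  default, with a switch.
* No implausible-energy filter is applied to recalls; if such cleaning is
  wanted it must happen upstream.
* HDAS, junk-food item lists and child BMI reference categories are consumed
  as inputs; their construction is out of scope.
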