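# dietdiv

Dietary diversity scoring and tertile association analysis for multi-day
24-hour dietary recall (24-HDR) cohorts.

Nutrition epidemiology lacks a standard way to quantify how *varied* a diet
is, which is one reason associations between dietary diversity and health
outcomes are inconsistent across studies. `dietdiv` implements two
complementary indices for cohorts with repeated 24-HDRs and the statistical
surface used to relate them to diet quality and health status — aimed at
epidemiologists and nutrition researchers working with recall-level intake
data (participant × day × food × amount).

## The indices

**Dietary diversity score (DDS).** For each of five food groups
*g* ∈ {cereals, dairy, fruits, vegetables, protein-rich foods} and each age
group, a participant's ratio

&nbsp;&nbsp;&nbsp;&nbsp;r<sub>ig</sub> = (distinct foods of group *g* eaten by participant *i* over 3 recall days) / (distinct foods of group *g* eaten by the whole age group)

is scored by its age-specific quartile — 1.5, 3, 4.5 or 6 points
(FG_DDS) — and the five group scores are summed:

&nbsp;&nbsp;&nbsp;&nbsp;DDS<sub>i</sub> = Σ<sub>g</sub> FG_DDS<sub>ig</sub> ∈ [7.5, 30].

Condiments, sauces and energy-dense nutrient-poor foods are excluded from
group counting (but not from intake totals).

**Food variety score (FVS).** Distinct foods ÷ total foods (with
multiplicity) the participant consumed over the first 3 recall days,
in (0, 1].

Around the scores, the package derives the usual diet-quality metrics
(energy, %TEI macronutrients by Atwater 4/9/4, fiber, energy density over
solid foods, NOVA-4 ultra-processed energy share with age/sex quintiles, FFQ
propensities, HOMA-IR, BMI categories) and runs the tertile analysis:
marginal means with 95% CIs (via `emmeans`), Bonferroni-corrected pairwise
contrasts, and logistic regression of overweight/obesity on score tertiles
adjusted for sex, age, country, parental education (ISCED) and optionally
energy. A synthetic-cohort generator with injectable diversity effects makes
the whole pipeline testable without access-restricted study data.

## Worked example

```r
library(dietdiv)

cohort <- simulate_cohort(sim_config(seed = 42,
  n_per_age_group = c(child = 200, teen = 200, adult = 200)))
scores <- score_diversity(cohort$recalls, cohort$catalogue,
                          cohort$participants)
scores[1, c("participant_id", "dds", "dds_tertile", "fvs", "fvs_tertile")]
#>   participant_id   dds dds_tertile   fvs fvs_tertile
#> 1 P00001          10.5 low         0.926 high
```

Participant `P00001` scored 1.5 points (bottom age-specific quartile) in
cereals, dairy and protein foods and 3 points in fruits and vegetables, for
a DDS of 10.5 — a low-diversity diet for their age group — while their FVS
of 0.926 (nearly every food eaten was distinct) lands in the high tertile:
the two indices deliberately capture different things.

```r
profiles <- upf_quintiles(diet_quality_profiles(cohort$recalls,
                                                cohort$catalogue),
                          cohort$participants)
dat <- merge(merge(scores, profiles, by = "participant_id"),
             cohort$participants[, c("participant_id", "sex", "age_years",
                                     "country", "isced", "bmi_category")],
             by = "participant_id")
adults <- dat[dat$age_group == "adult", ]
mm <- tertile_marginal_means(adults, "fiber_g_day", "dds_tertile")
mm$means
#>   tertile  mean ci_low ci_high  n
#> 1 low      30.3   28.6    32.0 68
#> 2 medium   41.9   40.4    43.5 78
#> 3 high     53.2   51.4    55.1 54
```

Mean fiber intake climbs from 30.3 to 53.2 g/day across adult DDS tertiles
(this cohort was simulated with a positive fiber effect), and
`pairwise_bonferroni(mm$emm)` flags all three pairwise differences as
significant after correction. The adjusted logistic model returns the
overweight/obesity odds ratios per tertile versus the low reference:

```r
fit_overweight_logistic(adults, "dds_tertile", model = "a")
#>   contrast      odds_ratio ci_low ci_high p_value model n_used
#> 1 medium vs low      0.578  0.287    1.17   0.125 a        200
#> 2 high vs low        0.800  0.374    1.71   0.566 a        200
```

At n = 200 adults the intervals are wide and cross 1; the injected
protective effect is recovered reliably at cohort scale (see the acceptance
checks below).

## Analysis workflow

The `analysis/` scripts run the full study pipeline over a simulated
3035-participant cohort and write all tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # results/data/{foods,participants,recalls,truth}.csv
Rscript analysis/02_score_diversity.R # results/scores.csv
Rscript analysis/03_diet_quality.R    # results/quality.csv
Rscript analysis/04_associations.R    # tertile tables + odds ratios
```

`run_pipeline()` does the same in one call, from a config or from the three
input CSVs.

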