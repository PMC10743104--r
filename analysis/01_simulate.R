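#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: a food catalogue, 3035 participants in
# three age groups across eight countries, and three 24-h recall days per
# participant, with the default injected diversity effects (more distinct
# fruit/vegetable foods, more fiber, less ultra-processed energy and lower
# adult overweight odds as the latent diversity propensity rises).
# Writes results/data/{foods,participants,recalls,truth}.csv.

library(dietdiv)

cfg <- sim_config(seed = 20240301)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/data")

cat(sprintf("catalogue: %d foods (%d NOVA-4)\n", nrow(cohort$catalogue),
            sum(cohort$catalogue$nova_class == 4)))
cat(sprintf("participants: %d (%s)\n", nrow(cohort$participants),
            paste(names(table(cohort$participants$age_group)),
                  table(cohort$participants$age_group), collapse = ", ",
                  sep = "=")))
cat(sprintf("recall rows: %d over %d days each\n", nrow(cohort$recalls),
            cfg$n_recall_days))
cat("wrote results/data/\n")
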