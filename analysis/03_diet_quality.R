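#!/usr/bin/env Rscript
# Derive per-participant diet-quality metrics from the selected recall days:
# daily energy, percent-of-energy macronutrients (Atwater 4/9/4), fiber,
# dietary energy density over solid foods, ultra-processed (NOVA 4) energy
# share with age- and sex-specific quintiles, and HOMA-IR where biomarkers
# exist. Writes results/quality.csv.

library(dietdiv)

catalogue <- read_food_catalogue("results/data/foods.csv")
participants <- read_participants("results/data/participants.csv")
recalls <- read_recalls("results/data/recalls.csv", catalogue)

profiles <- diet_quality_profiles(recalls, catalogue)
profiles <- upf_quintiles(profiles, participants)
profiles$homa_ir <- homa_ir(
  participants$glucose_mmol_l[match(profiles$participant_id,
                                    participants$participant_id)],
  participants$insulin_mU_l[match(profiles$participant_id,
                                  participants$participant_id)])

out <- profiles
for (cl in grep("pct_tei$", names(out), value = TRUE)) {
  out[[cl]] <- round(out[[cl]], 1)
}
readr::write_csv(out, "results/quality.csv")

cat(sprintf("energy: %.0f kcal/day (mean);  energy density %.2f kcal/g\n",
            mean(profiles$energy_kcal_day),
            mean(profiles$energy_density_kcal_per_g, na.rm = TRUE)))
cat(sprintf("macronutrients (%%TEI): protein %.1f, fat %.1f, carb %.1f\n",
            mean(profiles$protein_pct_tei), mean(profiles$fat_pct_tei),
            mean(profiles$carb_pct_tei)))
cat(sprintf("UPF energy share: %.1f%% (mean);  fiber %.1f g/day\n",
            mean(profiles$upf_pct_tei), mean(profiles$fiber_g_day)))
cat(sprintf("HOMA-IR available for %d participants\n",
            sum(!is.na(profiles$homa_ir))))
cat("wrote results/quality.csv\n")
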