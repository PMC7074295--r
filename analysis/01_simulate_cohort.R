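#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic ultrasound cohort.
#
# Draws the default 1115-subject cohort (four scheduled scans at ~17, 25,
# 33 and 37 weeks plus delivery), writes it as plain CSV, and reports how
# the realized cohort compares with its calibration targets: birth weight
# 3562 g (SD 478), delivery at 280 d (SD 8.34), macrosomia near 17.5%.

library(fetalens)

seed <- 20260927L
cohort <- simulate_cohort(sim_config(n_subjects = 1115, seed = seed))
write_cohort(cohort, "results/cohort")

s <- cohort$subjects
cat(sprintf("cohort: %d subjects, %d ultrasound visits (seed %d)\n",
            nrow(s), nrow(cohort$visits), seed))
cat(sprintf("birth weight: mean %.0f g, SD %.0f g (targets 3562 / 478)\n",
            mean(s$birth_weight), sd(s$birth_weight)))
cat(sprintf("gestational age at delivery: %.1f d (SD %.2f)\n",
            mean(s$birth_ga), sd(s$birth_ga)))
cat(sprintf("macrosomia %.1f%% (target ~17.5%%), LGA %.1f%%\n",
            100 * mean(s$macrosomia), 100 * mean(s$lga)))

split <- stratified_split(s$id, 0.7,
                          interaction(s$macrosomia, s$lga, drop = TRUE),
                          seed = seed)
cat(sprintf("stratified 70/30 split: %d train / %d test\n",
            length(split$train), length(split$test)))
# downstream stages re-derive the cohort and split from the same seed
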