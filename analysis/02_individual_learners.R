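#!/usr/bin/env Rscript
# Stage 2 — fit individual learners and score them on the held-out test set.
#
# Each learner couples one growth-model variant with one EFW formula.
# To keep this driver quick it uses all four model variants crossed with
# six formulas (the full 4 x 26 = 104 design is identical in shape);
# fits follow the evaluation protocol: training rows plus the test
# subjects' ultrasound rows, test birth weights masked.

library(fetalens)

seed <- 20260927L
cohort <- simulate_cohort(sim_config(n_subjects = 1115, seed = seed))
s <- cohort$subjects
split <- stratified_split(s$id, 0.7,
                          interaction(s$macrosomia, s$lga, drop = TRUE),
                          seed = seed)

grid <- learner_grid(formula_ids = 1:6)
cat(sprintf("fitting %d learners (%d would be the full design)\n",
            nrow(grid), nrow(learner_grid())))
fits <- suppressWarnings(fit_learners(cohort, grid,
                                      mask_birth_ids = split$test))
panel <- build_learner_panel(cohort, fits)
truth <- s[match(split$test, s$id), c("id", "macrosomia", "lga")]
tabs <- evaluate_all(panel_subset(panel, split$test), truth)

dir.create("results", showWarnings = FALSE)
write.csv(tabs$learner_metrics, "results/learner_metrics.csv",
          row.names = FALSE)
lm <- tabs$learner_metrics
best <- lm[lm$target == "macrosomia", ]
best <- best[which.max(best$youden), ]
cat(sprintf("best macrosomia learner: %s (Youden %.3f, AUC %.3f)\n",
            best$learner, best$youden, best$auc))
cat("wrote results/learner_metrics.csv\n")
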