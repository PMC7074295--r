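#!/usr/bin/env Rscript
# Stage 4 — the two simulation studies behind the headline claims.
#
# (a) Fixed-effect recovery: simulate cohorts from known growth-model
#     parameters, refit, summarize relative bias and Wald coverage.
# (b) Ensembles versus the best individual learner on cohorts with
#     redundant/noisy learners (scaled design: n = 300, 20 replicates,
#     logistic+quadratic x formulas 1-6, SCAD and MCP selection).

library(fetalens)

seed <- 20260927L
dir.create("results", showWarnings = FALSE)

rows <- NULL
for (model in c("logistic", "quadratic")) {
  st <- recovery_study(model, n = 500, n_reps = 20, seed = seed)
  cat(sprintf("%s recovery: bias%% = (%s); coverage = (%s)\n", model,
              paste(sprintf("%.2f", st$bias_pct), collapse = ", "),
              paste(sprintf("%.2f", st$coverage), collapse = ", ")))
  rows <- rbind(rows, data.frame(model = model, effect = 1:3,
                                 truth = st$truth, bias_pct = st$bias_pct,
                                 coverage = st$coverage))
}
write.csv(rows, "results/recovery_study.csv", row.names = FALSE)

st <- ensemble_study(n_reps = 20, n_subjects = 300, seed = seed)
cat(sprintf("best individual learner: %s (mean Youden %.3f)\n",
            names(st$best_individual), st$best_individual))
print(round(st$ensemble_means, 3))
write.csv(data.frame(outcome = names(st$means), mean_youden = st$means),
          "results/ensemble_study.csv", row.names = FALSE)
cat("wrote results/recovery_study.csv and results/ensemble_study.csv\n")
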