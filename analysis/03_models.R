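#!/usr/bin/env Rscript
# Robust predictor selection: per-drug propensity and remission LASSO
# models with 5-fold CV, the 1-SE rule, and bootstrap sign-stability,
# reported in the style of a model-accuracy table (prevalence, holdout
# AROC, number of robust predictors per model family).

suppressMessages({library(stratarx); library(data.table)})

claims <- "results/claims"
members <- fread(file.path(claims, "members.csv"))
medical <- fread(file.path(claims, "medical.csv"))
medical[, service_date := as.Date(service_date)]
pharmacy <- fread(file.path(claims, "pharmacy.csv"))
pharmacy[, fill_date := as.Date(fill_date)]
episodes <- fread("results/episodes.csv")
episodes[, start_date := as.Date(start_date)]

features <- build_features(episodes, medical, pharmacy)
cat(sprintf("feature matrix: %d episodes x %d binary predictors\n",
            nrow(features$X), ncol(features$X)))

drugs <- episodes[, .N, by = drug_label][N >= 300, drug_label]
rows <- list()
models <- list()
for (dg in drugs) {
  y <- as.integer(episodes$drug_label == dg)
  prop <- fit_propensity(features, episodes, members, dg,
                         K = 100, B = 12, seed = 1)
  rem <- fit_remission(features, episodes, members, dg,
                       K = 100, B = 12, seed = 1)
  d <- stratarx:::model_design(features, episodes, members, 100, y)
  rows[[dg]] <- data.table(
    drug = dg,
    prevalence = mean(y),
    propensity_aroc = evaluate_aroc(prop, d$X, y, scheme = "holdout"),
    propensity_predictors = length(prop$features) + 2L,
    remission_prevalence = mean(episodes$remission[episodes$drug_label == dg]),
    remission_predictors = length(rem$features) + 2L)
  models[[dg]] <- list(propensity = prop, remission = rem)
  cat(sprintf("%-14s propensity: %2d robust predictors; remission: %2d\n",
              dg, length(prop$features), length(rem$features)))
}
summary <- rbindlist(rows)
print(summary, digits = 3)
fwrite(summary, "results/models_summary.csv")
dir.create("scratch", showWarnings = FALSE)
saveRDS(models, "scratch/models.rds")  # intermediate for the next stage
cat("wrote results/models_summary.csv\n")
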