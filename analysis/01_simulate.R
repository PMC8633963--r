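#!/usr/bin/env Rscript
# Simulate the study cohort: a synthetic claims bundle (members, medical
# claims, pharmacy fills) with known feature->drug propensity and
# feature->remission structure, written as the three standard CSVs plus
# ground truth.  Downstream scripts consume only the CSVs, mirroring an
# analysis that starts from a claims extract.

suppressMessages(library(stratarx))

out <- "results/claims"
cfg <- synth_config(
  n_patients = 8000,
  n_features = 12,
  drugs = c("Sertraline", "Citalopram", "Bupropion", "Fluoxetine",
            "Escitalopram", "Other"),
  seed = 20260919
)
bundle <- generate_claims(cfg)
paths <- write_claims(bundle, out)

cat(sprintf("patients: %d\n", nrow(bundle$members)))
cat(sprintf("episodes (truth): %d\n", nrow(bundle$truth$episodes)))
cat(sprintf("pharmacy fills: %d; medical claims: %d\n",
            nrow(bundle$pharmacy), nrow(bundle$medical)))
cat(sprintf("true remission rate: %.1f%%\n",
            100 * mean(bundle$truth$episodes$remit)))
cat("wrote:", paste(basename(paths), collapse = ", "), "->", out, "\n")
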