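#!/usr/bin/env Rscript
# Build treatment episodes from the pharmacy fills, classify treatments,
# apply the 4-condition surrogate remission index with the clinician
# override, and the 1-year-and-100-days eligibility filter.

suppressMessages({library(stratarx); library(data.table)})

claims <- "results/claims"
members <- fread(file.path(claims, "members.csv"))
members[, `:=`(cov_start = as.Date(cov_start), cov_end = as.Date(cov_end))]
medical <- fread(file.path(claims, "medical.csv"))
medical[, service_date := as.Date(service_date)]
pharmacy <- fread(file.path(claims, "pharmacy.csv"))
pharmacy[, fill_date := as.Date(fill_date)]

episodes <- label_episodes(pharmacy, medical, members)
dropped <- attr(episodes, "dropped")

cat(sprintf("episodes built: %d (dropped: %s)\n", nrow(episodes),
            paste(names(dropped), dropped, sep = "=", collapse = ", ")))
cat(sprintf("remission rate: %.1f%% (%.1f%% from clinician codes)\n",
            100 * mean(episodes$remission),
            100 * mean(episodes$remission_source == "clinician_code")))
print(episodes[, .N, keyby = drug_label])

fwrite(episodes, "results/episodes.csv")
fwrite(cohort_summary(members, episodes), "results/cohort_summary.csv")
cat("wrote results/episodes.csv, results/cohort_summary.csv\n")
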