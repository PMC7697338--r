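#!/usr/bin/env Rscript
# Cohort simulation and descriptive comparison tables.
#
# Simulates a development cohort (n = 1004) and an external validation
# cohort (n = 136) under the default generative model, derives the Youden's
# J cutoff for the interface volume on the development cohort only, applies
# it to both, and writes the response-stratified and group-stratified
# comparison tables (the analogues of a study's "characteristics of
# patients" tables).
#
# Findings with seed 11: the high-interface group shows the lower pCR rate
# in both cohorts (development 38.4% vs 41.6%, validation 28.6% vs 42.5%),
# and HER2 status dominates the response-stratified table, as built into the
# generative model. The Youden cutoff estimate itself is noisy for a marker
# of this strength (1.92 cm^3 here vs the generative threshold 2.36 cm^3,
# J = 0.03): with a conditional odds ratio of 1.4 the optimal-cutpoint
# location is weakly identified in a single cohort, which is exactly why the
# original design froze the development-cohort cutoff before validation.

suppressMessages(library(tfivolume))
dir.create("results", showWarnings = FALSE)
seed <- 11L

dev <- simulate_cohort(cohort_config(n_patients = 1004L, seed = seed + 101L))
val <- simulate_cohort(cohort_config(n_patients = 136L, seed = seed + 202L))

cut <- youden_cutoff(dev$interface_volume_cm3, 1L - dev$pcr)
dev <- dichotomize_interface(dev, cut$cutoff)
val <- dichotomize_interface(val, cut$cutoff)      # development cutoff reused

by_response <- compare_groups(dev, by = "pcr")
by_group <- compare_groups(dev, by = "interface_group",
                           vars = c("age", "bmi", "interface_volume_cm3",
                                    "er", "pr", "her2", "ki67", "menopause"))
write.csv(dev, "results/02_cohort_development.csv", row.names = FALSE)
write.csv(val, "results/02_cohort_validation.csv", row.names = FALSE)
write.csv(by_response, "results/02_by_response_development.csv", row.names = FALSE)
write.csv(by_group, "results/02_by_interface_group_development.csv", row.names = FALSE)

rate <- function(d, g) 100 * mean(d$pcr[d$interface_group == g])
cat("Cohort simulation (seed", seed, "):\n")
cat(sprintf("  derived Youden cutoff: %.2f cm^3 (J = %.3f)\n", cut$cutoff, cut$j))
cat(sprintf("  development pCR rate: %.1f%% overall; low %.1f%% vs high %.1f%%\n",
            100 * mean(dev$pcr), rate(dev, "Low"), rate(dev, "High")))
cat(sprintf("  validation  pCR rate: %.1f%% overall; low %.1f%% vs high %.1f%%\n",
            100 * mean(val$pcr), rate(val, "Low"), rate(val, "High")))
iv <- by_response[by_response$variable == "interface_volume_cm3", ]
cat(sprintf("  interface volume by response (development): p = %.3g\n", iv$p[1]))
cat("  tables written under results/02_*.csv\n")
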