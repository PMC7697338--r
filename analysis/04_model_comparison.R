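#!/usr/bin/env Rscript
# Added value of the interface biomarker: nested model comparison.
#
# Builds the conventional model (selected clinical predictors without the
# interface group) and the combined model (conventional + interface group)
# on both simulated cohorts, and compares them with the DeLong test on the
# fitted risks, continuous NRI, IDI, and AIC. Also reports the Spearman
# correlation between the interface volume and tumor volume proxies in the
# measurement table of script 01, when present.
#
# Findings with seed 11: the added value of a conditional-OR-1.4 marker is
# small and cohort-dependent -- the development cohort shows essentially no
# AUC gain (0.687 -> 0.688, DeLong p = 0.85) and a slightly worse AIC, while
# the validation draw happens to show a modest gain (AUC 0.752 -> 0.761, AIC
# down 0.2). Both patterns are typical single-cohort outcomes for a weak
# real marker: discrimination metrics move little even when the effect is
# genuinely present. The measured interface volume tracks its ground truth
# almost perfectly (Spearman rho 0.99) and correlates only moderately with
# tumor volume (rho 0.50), i.e. it is not a tumor-size surrogate.

suppressMessages(library(tfivolume))
dir.create("results", showWarnings = FALSE)
seed <- 11L

dev <- simulate_cohort(cohort_config(n_patients = 1004L, seed = seed + 101L))
val <- simulate_cohort(cohort_config(n_patients = 136L, seed = seed + 202L))
cut <- youden_cutoff(dev$interface_volume_cm3, 1L - dev$pcr)
dev <- dichotomize_interface(dev, cut$cutoff)
val <- dichotomize_interface(val, cut$cutoff)

conventional <- c("er", "pr", "her2", "ki67")
rows <- lapply(list(development = dev, validation = val), function(coh) {
  mc <- compare_models(coh, conventional)
  data.frame(auc_conventional = mc$auc_conventional,
             auc_combined = mc$auc_combined, delong_p = mc$delong_p,
             nri = mc$nri, nri_p = mc$nri_p, idi = mc$idi, idi_p = mc$idi_p,
             aic_conventional = mc$aic_conventional,
             aic_combined = mc$aic_combined)
})
tab <- cbind(cohort = names(rows), do.call(rbind, rows))
write.csv(tab, "results/04_model_comparison.csv", row.names = FALSE)

cat("Model comparison (seed", seed, "):\n")
for (i in 1:2)
  cat(sprintf("  %s: AUC %.3f -> %.3f (DeLong p = %.3f), NRI %+.3f, IDI %+.4f, AIC %.1f -> %.1f\n",
              tab$cohort[i], tab$auc_conventional[i], tab$auc_combined[i],
              tab$delong_p[i], tab$nri[i], tab$idi[i],
              tab$aic_conventional[i], tab$aic_combined[i]))

f01 <- "results/01_phantom_recovery.csv"
if (file.exists(f01)) {
  pt <- read.csv(f01)
  sm <- spearman_matrix(pt[, c("measured_interface_cm3", "measured_tumor_cm3",
                               "true_interface_cm3")])
  cat(sprintf("  Spearman rho, measured interface vs tumor volume: %.2f; vs truth: %.2f\n",
              sm[1, 2], sm[1, 3]))
}
cat("  table written to results/04_model_comparison.csv\n")
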