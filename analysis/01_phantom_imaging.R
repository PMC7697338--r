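#!/usr/bin/env Rscript
# Imaging stage on synthetic ground truth.
#
# Generates a batch of breast-MRI phantoms spanning tumor sizes and
# fat-contact fractions, runs the full measurement front end (chest-wall
# interpolation -> breast mask -> two-stage k-means -> 6-adjacency interface
# counting), and tabulates measured against ground-truth volumetrics.
#
# Findings with the shipped defaults (seed 11): noiseless phantoms are
# recovered exactly; at the default noise (sd 10, fat/fibroglandular
# separation 5 sigma) per-tissue Dice stays above 0.94 and tumor volume
# error below 3%, while the interface volume -- a one-voxel-thin shell -- is
# the most noise-sensitive of the five quantities.

suppressMessages(library(tfivolume))
dir.create("results", showWarnings = FALSE)
seed <- 11L

base <- phantom_config()            # 64 x 128 x 128 at 3 x 0.8 x 0.8 mm
rows <- list()
for (i in 1:10) {
  cfg <- phantom_config(tumor_radius_mm = c(8, 10, 11, 12, 14)[(i - 1) %% 5 + 1],
                        tumor_margin_contact = c(0.3, 0.9)[(i - 1) %/% 5 + 1],
                        noise_sd = base$noise_sd, seed = seed + i)
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  mask <- build_breast_mask(ph$study, wall)
  lab <- cluster_tissues(ph$study, mask, seed = seed + i)
  measured <- summarize_volumes(lab)
  truth <- ph$truth$true_volumes
  dice <- vapply(1:3, function(k)
    2 * sum(unclass(lab) == k & unclass(ph$truth$labels) == k) /
      (sum(unclass(lab) == k) + sum(unclass(ph$truth$labels) == k)), 0)
  rows[[i]] <- data.frame(
    phantom = i, tumor_radius_mm = cfg$tumor_radius_mm,
    margin_contact = cfg$tumor_margin_contact,
    dice_fat = dice[1], dice_fgt = dice[2], dice_tumor = dice[3],
    measured_interface_cm3 = measured$interface_volume_cm3,
    true_interface_cm3 = truth$interface_volume_cm3,
    measured_tumor_cm3 = measured$tumor_volume_cm3,
    true_tumor_cm3 = truth$tumor_volume_cm3)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/01_phantom_recovery.csv", row.names = FALSE)

cat("Phantom imaging recovery (seed", seed, "):\n")
cat(sprintf("  min per-tissue Dice: %.3f\n",
            min(tab$dice_fat, tab$dice_fgt, tab$dice_tumor)))
cat(sprintf("  median |interface error|: %.2f cm^3 (true median %.2f cm^3)\n",
            median(abs(tab$measured_interface_cm3 - tab$true_interface_cm3)),
            median(tab$true_interface_cm3)))
cat(sprintf("  median tumor volume error: %.1f%%\n",
            100 * median(abs(tab$measured_tumor_cm3 / tab$true_tumor_cm3 - 1))))
cat("  table written to results/01_phantom_recovery.csv\n")
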